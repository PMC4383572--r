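# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

abort <- function(...) stop(..., call. = FALSE)

# locale-independent ordering so tie-breaking by probe id is reproducible
radix_order <- function(x) order(x, method = "radix")

# probes x groups matrix of group means
row_group_means <- function(mat, groups) {
  groups <- factor(groups)
  sums <- t(rowsum(t(mat), group = groups, reorder = TRUE))
  counts <- as.integer(table(groups))
  sweep(sums, 2L, counts, "/")
}

# pooled within-group SD per row (probes x samples matrix)
row_pooled_sd <- function(mat, groups) {
  groups <- factor(groups)
  n <- ncol(mat)
  k <- nlevels(groups)
  if (n <= k) abort("need more samples than groups for a pooled SD")
  gm <- row_group_means(mat, groups)
  counts <- as.integer(table(groups))
  ssw <- rowSums(mat^2) - as.vector(gm^2 %*% counts)
  sqrt(pmax(ssw, 0) / (n - k))
}

# effective per-sample class label: explicit class_label when present,
# otherwise the treatment label itself
sample_classes <- function(metadata) {
  cls <- metadata$treatment
  if (!is.null(metadata$class_label)) {
    has <- !is.na(metadata$class_label) & nzchar(metadata$class_label)
    cls[has] <- metadata$class_label[has]
  }
  cls
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != round(x) || x < min)
    abort(sprintf("'%s' must be a single integer >= %d", name, min))
  as.integer(x)
}

check_number <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x > max)
    abort(sprintf("'%s' must be a single number in [%s, %s]", name, min, max))
  as.numeric(x)
}

# format doubles so that read.delim() recovers them bit-exactly
format_full <- function(x) sprintf("%.17g", x)
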