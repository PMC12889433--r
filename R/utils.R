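# Internal helpers shared across modules.

# Deterministic sub-stream seed for a named generator component. All
# randomness in a dataset flows from one config seed; each component draws
# from its own derived stream so that adding a component never perturbs the
# draws of another.
derive_seed <- function(seed, component) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(component))
  h <- sum(utf8ToInt(component) * seq_along(utf8ToInt(component)))
  as.integer((as.numeric(seed) * 48271 + h * 7919) %% 2147483647)
}

# Validate a two-level condition column.
check_condition <- function(x, arg = "condition") {
  bad <- setdiff(unique(as.character(x)), c("healthy", "AD"))
  if (length(bad) > 0) {
    abort(sprintf("`%s` must be 'healthy' or 'AD'; found: %s",
                  arg, paste(bad, collapse = ", ")))
  }
  invisible(x)
}

# Coerce a (cluster, delta)-like input to a named numeric vector.
as_named_numeric <- function(x, value_col = "delta", name_col = "cluster") {
  if (is.data.frame(x)) {
    if (!all(c(name_col, value_col) %in% names(x))) {
      abort(sprintf("data frame input must have columns '%s' and '%s'",
                    name_col, value_col))
    }
    return(setNames(as.numeric(x[[value_col]]), as.character(x[[name_col]])))
  }
  v <- as.numeric(x)
  names(v) <- names(x) %||% as.character(seq_along(v))
  v
}

# Pooled (n-1 weighted) standard deviation of two groups.
pooled_sd <- function(a, b) {
  na <- length(a); nb <- length(b)
  sqrt(((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / (na + nb - 2))
}
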