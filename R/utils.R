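# internal validation helpers

.stop_input <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

.check_expression_matrix <- function(x, what = "expression matrix") {
  if (!is.matrix(x) || !is.numeric(x))
    .stop_input("%s must be a numeric matrix", what)
  if (is.null(rownames(x)) || is.null(colnames(x)))
    .stop_input("%s must have feature rownames and sample colnames", what)
  if (anyDuplicated(rownames(x)))
    .stop_input("duplicate feature id in %s: '%s'", what,
                rownames(x)[duplicated(rownames(x))][1L])
  if (anyDuplicated(colnames(x)))
    .stop_input("duplicate sample id in %s: '%s'", what,
                colnames(x)[duplicated(colnames(x))][1L])
  if (any(!is.finite(x)))
    .stop_input("%s contains non-finite values", what)
  if (any(x < 0))
    .stop_input("%s contains negative values", what)
  invisible(x)
}

# population (ddof 0) standard deviation by row
.row_sd_pop <- function(x) {
  m <- rowMeans(x)
  sqrt(rowMeans((x - m)^2))
}

.is_count <- function(x) length(x) >= 1 && is.numeric(x) &&
  all(is.finite(x)) && all(x > 0) && all(x == round(x))
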