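#' @keywords internal
"_PACKAGE"

#' @importFrom stats cor median pchisq phyper pnorm qnorm quantile rnorm runif sd setNames t.test var
#' @importFrom utils combn read.delim write.table head
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

# canonical key for an unordered gene pair
edge_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "\r")
}

# population (divide-by-n) standard deviation
pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

# clip p-values away from 0 and 1 so the normal quantile stays finite
clip_p <- function(p, lo = 1e-300, hi = 1 - 1e-16) pmin(pmax(p, lo), hi)

#' Derive a stage-specific RNG seed from a master seed
#'
#' Hashes a label into a 31-bit offset so that every pipeline stage draws from
#' its own reproducible stream while all randomness flows from one top-level
#' seed.
#'
#' @param seed integer master seed.
#' @param label character stage name.
#' @return an integer seed below 2^31.
#' @export
derive_seed <- function(seed, label) {
  codes <- utf8ToInt(label)
  h <- sum(codes * seq_along(codes))
  as.integer((abs(as.numeric(seed)) * 1009 + h * 31) %% 2147483629)
}

stop_if_missing_genes <- function(genes, known, what = "gene") {
  missing <- setdiff(genes, known)
  if (length(missing) > 0L) {
    stop(sprintf("unknown %s(s): %s", what,
                 paste(head(sort(missing), 10L), collapse = ", ")),
         call. = FALSE)
  }
  invisible(TRUE)
}
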