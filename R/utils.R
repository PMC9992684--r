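#' Derive a reproducible sub-stream seed
#'
#' All randomised stages derive their own seed from one master seed plus a
#' counter path (stage name, modality, region id, round number, ...), so any
#' region or round can be re-run in isolation and reproduce the full run
#' bit for bit.
#'
#' @param master integer master seed.
#' @param ... integers and/or strings identifying the sub-stream.
#' @return an integer in [0, 2^31 - 2] usable with [set.seed()].
#' @export
substream_seed <- function(master, ...) {
  parts <- list(master, ...)
  h <- 0
  for (p in parts) {
    if (is.character(p)) {
      codes <- utf8ToInt(p)
      p <- sum(codes * seq_along(codes))
    }
    for (v in as.numeric(p)) {
      # 64-bit-safe LCG mix; stays below 2^53 so doubles are exact
      h <- (h * 69069 + v + 12345) %% 2147483647
    }
  }
  as.integer(h)
}

#' Evaluate an expression under a local RNG seed
#'
#' Sets the RNG seed for the duration of `expr` and restores the previous
#' global RNG state afterwards, so package internals never perturb the
#' caller's random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  expr
}

# truncated-normal draw by rejection; bounds are loose so this is cheap
rnorm_trunc <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  out <- rnorm(n, mean, sd)
  bad <- which(out < lower | out > upper)
  while (length(bad) > 0L) {
    out[bad] <- rnorm(length(bad), mean, sd)
    bad <- bad[out[bad] < lower | out[bad] > upper]
  }
  out
}

stop_if_not_scalar_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stop(sprintf("'%s' must be a single value in [0, 1]", name), call. = FALSE)
  }
}

#' Write a data frame as a TSV with fixed formatting
#'
#' All tabular pipeline outputs go through this writer: tab-separated, header,
#' no quoting, numeric columns rounded to 6 decimals. Fixed formatting makes
#' outputs diff-able across runs.
#'
#' @param df data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tsv6 <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.numeric(out[[j]]) && !is.integer(out[[j]])) {
      out[[j]] <- sprintf("%.6f", out[[j]])
      out[[j]][out[[j]] %in% c("NA", "NaN")] <- "NA"
    }
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
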