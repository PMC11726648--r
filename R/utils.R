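# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

#' @noRd
clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Stop with a consistent error class
#' @noRd
tp_stop <- function(..., class = "thinpatch_error", call. = FALSE) {
  stop(errorCondition(paste0(...), class = c(class, "thinpatch_error")))
}

#' @noRd
assert_scalar_number <- function(x, name, lo = -Inf, hi = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lo || x > hi)
    tp_stop(sprintf("'%s' must be a finite number in [%s, %s]", name, lo, hi),
            class = "thinpatch_config_error")
  invisible(x)
}

#' Zero-padded patch labels ("patch_0001", ...)
#' @noRd
patch_labels <- function(n_patches) sprintf("patch_%04d", seq_len(n_patches))

#' Parse patch labels or plain integers back to 1-based indices
#' @noRd
parse_patch_labels <- function(x) {
  x <- trimws(as.character(x))
  idx <- ifelse(grepl("^patch_[0-9]+$", x), sub("^patch_", "", x), x)
  out <- suppressWarnings(as.integer(idx))
  if (anyNA(out))
    tp_stop("unparseable patch labels: ", paste(utils::head(x[is.na(out)], 3), collapse = ", "))
  out
}
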