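#' Construct a domain-specific patch set
#'
#' @param indices 1-based patch indices; deduplicated and sorted.
#' @param name Short label (e.g. `"extremity"`).
#' @param provenance Free-text provenance (threshold, source maps).
#' @param n_patches Optional parcellation size for range checking.
#' @return Object of class `patch_set`.
#' @export
patch_set <- function(indices, name = "patch_set", provenance = "",
                      n_patches = NULL) {
  indices <- sort(unique(as.integer(indices)))
  if (length(indices) == 0L || anyNA(indices) || any(indices < 1L))
    tp_stop("patch set must be nonempty positive indices",
            class = "thinpatch_config_error")
  if (!is.null(n_patches) && any(indices > n_patches))
    tp_stop("patch indices exceed parcellation size",
            class = "thinpatch_config_error")
  structure(list(name = name, indices = indices,
                 provenance = as.character(provenance)),
            class = "patch_set")
}

#' @export
print.patch_set <- function(x, ...) {
  cat(sprintf("Patch set '%s': %d patches\n", x$name, length(x$indices)))
  if (nzchar(paste(x$provenance, collapse = "")))
    cat("  provenance:", paste(x$provenance, collapse = "; "), "\n")
  invisible(x)
}

#' @export
length.patch_set <- function(x) length(x$indices)

#' Best-matching network for a statistical surface map
#'
#' Ranks candidate network maps by spatial Pearson correlation with the
#' target map (computed over vertices finite in both) and returns the argmax
#' — a minimal functional stand-in for task-map-to-ICA-network cross-mapping.
#' Ranking uses the signed correlation. Candidates with zero variance are
#' excluded with a warning; exact ties break toward the lowest candidate
#' index (reported via a message).
#'
#' @param target Numeric per-vertex (or per-patch) map.
#' @param candidates List of numeric maps, all the same length as `target`.
#' @return List with `index`, `similarity` and the full `similarities`
#'   vector (`NA` for excluded candidates).
#' @export
best_matching_network <- function(target, candidates) {
  if (length(candidates) < 1) tp_stop("need at least one candidate map")
  lens <- vapply(candidates, length, integer(1))
  if (any(lens != length(target)))
    tp_stop("candidate maps must live on the target's space (length mismatch)",
            class = "thinpatch_validation_error")
  sims <- vapply(seq_along(candidates), function(i) {
    ok <- is.finite(target) & is.finite(candidates[[i]])
    if (sum(ok) < 3 || stats::sd(target[ok]) == 0 ||
        stats::sd(candidates[[i]][ok]) == 0) return(NA_real_)
    stats::cor(target[ok], candidates[[i]][ok])
  }, numeric(1))
  if (all(is.na(sims)))
    tp_stop("similarity undefined for every candidate (zero variance)",
            class = "thinpatch_validation_error")
  if (anyNA(sims))
    warning(sprintf("%d zero-variance candidates excluded", sum(is.na(sims))),
            call. = FALSE)
  best <- which(sims == max(sims, na.rm = TRUE))
  if (length(best) > 1)
    message("similarity tie broken toward candidate ", best[1])
  list(index = best[1], similarity = sims[best[1]], similarities = sims)
}

#' Project a binary surface mask onto the patch parcellation
#'
#' Patch \eqn{j} enters the set iff the fraction of its labelled vertices
#' covered by the mask is at least `overlap_threshold`. The vertex-to-patch
#' assignment comes from `labels` (1-based patch index per vertex, `NA` for
#' unassigned vertices).
#'
#' @param mask Binary (0/1) per-vertex vector.
#' @param labels Integer per-vertex patch labels (`NA` = unassigned).
#' @param overlap_threshold Minimum covered fraction of a patch's vertices
#'   (default 0.5).
#' @param name Name for the resulting patch set.
#' @return A [patch_set()]; provenance records the threshold.
#' @export
mask_to_patches <- function(mask, labels, overlap_threshold = 0.5,
                            name = "masked") {
  if (length(mask) != length(labels))
    tp_stop("mask and labels must share the vertex space",
            class = "thinpatch_validation_error")
  if (!all(mask %in% c(0, 1)))
    tp_stop("mask must be binary (0/1)", class = "thinpatch_validation_error")
  assert_scalar_number(overlap_threshold, "overlap_threshold", 0, 1)
  ok <- !is.na(labels)
  tot <- table(factor(labels[ok]))
  cov <- table(factor(labels[ok & mask == 1], levels = names(tot)))
  frac <- as.numeric(cov) / as.numeric(tot)
  keep <- as.integer(names(tot))[frac >= overlap_threshold]
  if (length(keep) == 0)
    tp_stop("mask covers no patch at threshold ", overlap_threshold,
            "; lower the overlap threshold",
            class = "thinpatch_config_error")
  patch_set(keep, name = name,
            provenance = sprintf("mask projection, overlap >= %g", overlap_threshold))
}

#' Union of two patch sets
#'
#' Combines domain maps (e.g. hand + leg) into one restriction set.
#'
#' @param a,b [patch_set()] objects on the same parcellation.
#' @return A [patch_set()] with concatenated provenance.
#' @export
union_patchsets <- function(a, b) {
  stopifnot(inherits(a, "patch_set"), inherits(b, "patch_set"))
  patch_set(union(a$indices, b$indices),
            name = paste(unique(c(a$name, b$name)), collapse = "+"),
            provenance = c(a$provenance, b$provenance))
}

#' Read / write patch-set files
#'
#' Plain text: one 1-based patch label per line (`patch_0042` or `42`),
#' `#`-prefixed comment lines carry name and provenance.
#'
#' @param path File path.
#' @return `read_patchset`: a [patch_set()].
#' @export
read_patchset <- function(path) {
  lines <- readLines(path)
  comments <- sub("^#\\s*", "", lines[startsWith(lines, "#")])
  body <- trimws(lines[!startsWith(lines, "#")])
  body <- body[nzchar(body)]
  if (length(body) == 0)
    tp_stop("empty patch-set file: ", path, class = "thinpatch_validation_error")
  name <- sub("^name:\\s*", "", comments[startsWith(comments, "name:")])
  prov <- comments[!startsWith(comments, "name:")]
  patch_set(parse_patch_labels(body),
            name = if (length(name)) name[1] else "patch_set",
            provenance = prov)
}

#' @param x A [patch_set()] to write.
#' @rdname read_patchset
#' @export
write_patchset <- function(x, path) {
  stopifnot(inherits(x, "patch_set"))
  lines <- c(paste0("# name: ", x$name),
             paste0("# ", x$provenance[nzchar(x$provenance)]),
             sprintf("patch_%04d", x$indices))
  writeLines(lines, path)
  invisible(path)
}
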