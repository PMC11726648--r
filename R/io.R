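# Readers/writers for the plain-text interchange formats shared by all
# pipeline stages. Schemas are strict: downstream statistics silently absorb
# malformed tables otherwise.

#' Read and validate a thickness matrix CSV
#'
#' Expected schema: header `subject_id, patch_0001, ..., patch_NNNN` with a
#' complete, gap-free 1-based patch sequence; one row per subject; all cells
#' present, finite and strictly positive (mm).
#'
#' @param path CSV path.
#' @return Numeric matrix (subjects x patches) with subject-id rownames.
#' @export
read_thickness <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1] != "subject_id")
    tp_stop("thickness file must start with a 'subject_id' column: ", path,
            class = "thinpatch_schema_error")
  pcols <- names(df)[-1]
  want <- patch_labels(length(pcols))
  if (!identical(pcols, want)) {
    gap <- setdiff(want, pcols)
    tp_stop("patch columns are not the complete sequence patch_0001..",
            sprintf("patch_%04d", length(pcols)),
            if (length(gap)) paste0(" (first missing: ", gap[1], ")") else "",
            class = "thinpatch_schema_error")
  }
  ids <- as.character(df$subject_id)
  if (anyDuplicated(ids))
    tp_stop("duplicate subject ids: ",
            paste(utils::head(unique(ids[duplicated(ids)]), 3), collapse = ", "),
            class = "thinpatch_schema_error")
  mat <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(mat) || anyNA(mat) || !all(is.finite(mat))) {
    bad <- which(is.na(mat) | !is.finite(mat), arr.ind = TRUE)[1, ]
    tp_stop(sprintf("missing/non-finite thickness at row %s, column %s",
                    ids[bad[1]], want[bad[2]]),
            class = "thinpatch_schema_error")
  }
  if (any(mat <= 0)) {
    bad <- which(mat <= 0, arr.ind = TRUE)[1, ]
    tp_stop(sprintf("non-positive thickness at row %s, column %s",
                    ids[bad[1]], want[bad[2]]),
            class = "thinpatch_schema_error")
  }
  dimnames(mat) <- list(ids, want)
  mat
}

#' @param x Subjects x patches matrix with rownames.
#' @rdname read_thickness
#' @export
write_thickness <- function(x, path) {
  stopifnot(is.matrix(x), !is.null(rownames(x)))
  df <- data.frame(subject_id = rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df) <- c("subject_id", patch_labels(ncol(x)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read and validate a demographics CSV
#'
#' Requires `subject_id`, `age` (> 0 years) and `sex` (`M`/`F`); patient
#' tables may add `handedness` (`R`/`L`/`A`) and nonnegative
#' `symptom_duration` / `diagnosis_duration` (months).
#'
#' @param path CSV path.
#' @return Validated data.frame.
#' @export
read_demographics <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "age", "sex")
  if (!all(need %in% names(df)))
    tp_stop("demographics must contain columns: ", paste(need, collapse = ", "),
            class = "thinpatch_schema_error")
  if (anyNA(df$age) || any(df$age <= 0))
    tp_stop("ages must be positive", class = "thinpatch_schema_error")
  if (!all(df$sex %in% c("M", "F")))
    tp_stop("sex must be 'M' or 'F'", class = "thinpatch_schema_error")
  if ("handedness" %in% names(df) && !all(df$handedness %in% c("R", "L", "A")))
    tp_stop("handedness must be 'R', 'L' or 'A'",
            class = "thinpatch_schema_error")
  for (nm in intersect(c("symptom_duration", "diagnosis_duration"), names(df)))
    if (anyNA(df[[nm]]) || any(df[[nm]] < 0))
      tp_stop(nm, " must be nonnegative", class = "thinpatch_schema_error")
  df
}

#' Read and validate a long-format clinical CSV
#'
#' Schema: `subject_id`, `visit` (BL/Y1/Y3), `measure`
#' (extremity/total_motor/cognitive), `value`. Checks score ranges
#' (extremity 0-80, MoCA 0-30) and the subscore consistency
#' `extremity <= total_motor` within each subject-visit.
#'
#' @param path CSV path.
#' @return Validated data.frame.
#' @export
read_clinical <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "visit", "measure", "value")
  if (!all(need %in% names(df)))
    tp_stop("clinical table must contain columns: ",
            paste(need, collapse = ", "), class = "thinpatch_schema_error")
  if (!all(df$visit %in% c("BL", "Y1", "Y3")))
    tp_stop("visit must be BL, Y1 or Y3", class = "thinpatch_schema_error")
  if (!all(df$measure %in% c("extremity", "total_motor", "cognitive")))
    tp_stop("measure must be extremity, total_motor or cognitive",
            class = "thinpatch_schema_error")
  if (anyNA(df$value)) tp_stop("missing clinical values",
                               class = "thinpatch_schema_error")
  ext <- df$measure == "extremity"
  if (any(df$value[ext] < 0 | df$value[ext] > 80))
    tp_stop("extremity subscore outside [0, 80]",
            class = "thinpatch_schema_error")
  cog <- df$measure == "cognitive"
  if (any(df$value[cog] < 0 | df$value[cog] > 30))
    tp_stop("MoCA score outside [0, 30]", class = "thinpatch_schema_error")
  wide <- merge(df[ext, c("subject_id", "visit", "value")],
                df[df$measure == "total_motor", c("subject_id", "visit", "value")],
                by = c("subject_id", "visit"))
  if (any(wide$value.x > wide$value.y))
    tp_stop("extremity subscore exceeds total motor score for some visits",
            class = "thinpatch_schema_error")
  df
}
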