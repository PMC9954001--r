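# Readers and writers for the pipeline's plain-text formats. Doses are
# always serialized in uM with the unit in the column name.

check_plate <- function(plate) {
  need <- c("sample_id", "treatment_id", "dose_a_um", "dose_b_um",
            "replicate", "raw_signal", "is_vehicle")
  missing_cols <- setdiff(need, names(plate))
  if (length(missing_cols))
    stop("plate table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  bad <- which(!is.finite(plate$raw_signal) | plate$raw_signal < 0)
  if (length(bad))
    stop("negative or non-numeric raw_signal at row(s): ",
         paste(utils::head(bad, 5L), collapse = ", "))
  bad <- which(!is.finite(plate$dose_a_um) | !is.finite(plate$dose_b_um) |
                 plate$dose_a_um < 0 | plate$dose_b_um < 0)
  if (length(bad))
    stop("unparseable or negative dose at row(s): ",
         paste(utils::head(bad, 5L), collapse = ", "))
  invisible(plate)
}

#' Read a long-format plate CSV
#'
#' Expects the documented schema (`sample_id, treatment_id, dose_a_um,
#' dose_b_um, replicate, raw_signal, is_vehicle[, flag]`); validation
#' errors name the offending column or row.
#'
#' @param path CSV file path.
#' @return A validated plate `data.frame`.
#' @export
read_plate_csv <- function(path) {
  plate <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (col in c("dose_a_um", "dose_b_um", "raw_signal"))
    if (col %in% names(plate)) plate[[col]] <- as.numeric(plate[[col]])
  if ("is_vehicle" %in% names(plate))
    plate$is_vehicle <- as.logical(plate$is_vehicle)
  if (!"flag" %in% names(plate)) plate$flag <- ""
  plate$flag[is.na(plate$flag)] <- ""
  check_plate(plate)
  plate
}

#' Write a plate table as CSV
#' @param plate Plate `data.frame`.
#' @param path Output path.
#' @export
write_plate_csv <- function(plate, path) {
  check_plate(plate)
  utils::write.csv(plate, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a gene x sample expression TSV
#'
#' First column = gene ids, header = sample ids. Group labels come either
#' from a two-column CSV (`sample, group`) or a named vector.
#'
#' @param path TSV file path.
#' @param groups Named character vector of group labels, or path to a
#'   `sample,group` CSV.
#' @return An [expression_table()].
#' @export
read_expression_tsv <- function(path, groups) {
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(tab[, -1L, drop = FALSE])
  rownames(m) <- tab[[1L]]
  if (is.character(groups) && length(groups) == 1L && file.exists(groups)) {
    gmap <- utils::read.csv(groups, stringsAsFactors = FALSE)
    groups <- stats::setNames(gmap$group, gmap$sample)
  }
  expression_table(m, groups)
}

#' Write an expression table as TSV (plus optional group map CSV)
#' @param expr An [expression_table()].
#' @param path Output TSV path.
#' @param groups_path Optional path for the `sample,group` CSV.
#' @export
write_expression_tsv <- function(expr, path, groups_path = NULL) {
  stopifnot(inherits(expr, "expression_table"))
  tab <- data.frame(gene = rownames(expr$intensity), expr$intensity,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE)
  if (!is.null(groups_path))
    utils::write.csv(data.frame(sample = names(expr$groups),
                                group = unname(expr$groups)),
                     groups_path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a Ct table CSV (`gene, group, replicate, ct`)
#' @param path CSV file path.
#' @return A `data.frame`.
#' @export
read_ct_csv <- function(path) {
  ct <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("gene", "group", "replicate", "ct")
  missing_cols <- setdiff(need, names(ct))
  if (length(missing_cols))
    stop("Ct table is missing column(s): ", paste(missing_cols, collapse = ", "))
  ct$ct <- as.numeric(ct$ct)
  if (anyNA(ct$ct)) stop("unparseable Ct value(s)")
  ct
}

#' Write a Ct table as CSV
#' @param ct Ct `data.frame`.
#' @param path Output path.
#' @export
write_ct_csv <- function(ct, path) {
  utils::write.csv(ct, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
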