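# Readers/writers for drug tables (SMI / CSV / TSV) and labeled pair tables
# (TSV / CSV), plus negative-pair sampling. Pairs are unordered: they are
# stored with drug_a < drug_b lexicographically, and a duplicate of the same
# unordered pair with a conflicting label is a schema error.

ddimage_io_error <- function(message) {
  structure(class = c("ddimage_io_error", "ddimage_error",
                      "error", "condition"),
            list(message = message, call = NULL))
}

.guess_sep <- function(path, format = NULL) {
  if (!is.null(format)) {
    return(switch(toupper(format), TSV = "\t", CSV = ",",
                  stop(ddimage_io_error(paste0("unknown format: ", format)))))
  }
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' Read a drug table (drug_id -> SMILES)
#'
#' Accepts SMI format (one `SMILES whitespace id` per line, no header) or
#' CSV/TSV with a header naming columns `drug_id` and `smiles`.
#'
#' @param path Input file.
#' @param format `"SMI"`, `"CSV"`, `"TSV"` or NULL (guessed from extension;
#'   `.smi` means SMI).
#' @return data.frame with columns drug_id, smiles.
#' @export
read_drug_table <- function(path, format = NULL) {
  if (!file.exists(path)) {
    stop(ddimage_io_error(paste0("drug table not found: ", path)))
  }
  is_smi <- if (!is.null(format)) toupper(format) == "SMI"
            else grepl("\\.smi$", path, ignore.case = TRUE)
  if (is_smi) {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    parts <- strsplit(trimws(lines), "[ \t]+")
    bad <- which(vapply(parts, length, 0L) < 2L)
    if (length(bad) > 0L) {
      stop(ddimage_io_error(sprintf(
        "SMI line %d lacks an id after the SMILES", bad[1])))
    }
    return(data.frame(drug_id = vapply(parts, `[[`, "", 2L),
                      smiles = vapply(parts, `[[`, "", 1L),
                      stringsAsFactors = FALSE))
  }
  sep <- .guess_sep(path, format)
  tab <- utils::read.table(path, sep = sep, header = TRUE,
                           stringsAsFactors = FALSE, quote = "\"",
                           comment.char = "")
  for (col in c("drug_id", "smiles")) {
    if (!col %in% names(tab)) {
      stop(ddimage_io_error(paste0("drug table missing column: ", col)))
    }
  }
  tab[, c("drug_id", "smiles")]
}

#' Write a drug table
#'
#' @param drugs data.frame with drug_id, smiles.
#' @param path Output path; `.smi` writes SMI format, otherwise TSV/CSV by
#'   extension.
#' @export
write_drug_table <- function(drugs, path) {
  if (grepl("\\.smi$", path, ignore.case = TRUE)) {
    writeLines(paste(drugs$smiles, drugs$drug_id), path)
  } else {
    utils::write.table(drugs[, c("drug_id", "smiles")], path,
                       sep = .guess_sep(path), quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

# store unordered pairs canonically: drug_a < drug_b
normalize_pairs <- function(pairs) {
  swap <- pairs$drug_a > pairs$drug_b
  tmp <- pairs$drug_a[swap]
  pairs$drug_a[swap] <- pairs$drug_b[swap]
  pairs$drug_b[swap] <- tmp
  pairs
}

pair_key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")

#' Read a labeled pair table
#'
#' Requires a header naming columns `drug_a`, `drug_b`, `label`; labels must
#' coerce to 0/1. Malformed rows are reported with their line number. Pairs
#' are normalised to drug_a < drug_b; a self-pair or a duplicate unordered
#' pair carrying conflicting labels is an error.
#'
#' @param path Input file.
#' @param format `"TSV"`, `"CSV"` or NULL (guessed from extension).
#' @return data.frame with drug_a, drug_b, label (integer 0/1).
#' @export
read_pair_table <- function(path, format = NULL) {
  if (!file.exists(path)) {
    stop(ddimage_io_error(paste0("pair table not found: ", path)))
  }
  sep <- .guess_sep(path, format)
  tab <- utils::read.table(path, sep = sep, header = TRUE,
                           stringsAsFactors = FALSE, quote = "\"",
                           comment.char = "", colClasses = "character")
  for (col in c("drug_a", "drug_b", "label")) {
    if (!col %in% names(tab)) {
      stop(ddimage_io_error(paste0("pair table missing column: ", col)))
    }
  }
  lab_chr <- trimws(tab$label)
  bad <- which(!lab_chr %in% c("0", "1"))
  if (length(bad) > 0L) {
    stop(ddimage_io_error(sprintf(
      "line %d: label '%s' is not 0/1", bad[1] + 1L, lab_chr[bad[1]])))
  }
  self <- which(tab$drug_a == tab$drug_b)
  if (length(self) > 0L) {
    stop(ddimage_io_error(sprintf("line %d: self-pair %s", self[1] + 1L,
                                  tab$drug_a[self[1]])))
  }
  pairs <- normalize_pairs(data.frame(drug_a = tab$drug_a,
                                      drug_b = tab$drug_b,
                                      label = as.integer(lab_chr),
                                      stringsAsFactors = FALSE))
  key <- pair_key(pairs$drug_a, pairs$drug_b)
  conflict <- tapply(pairs$label, key, function(x) length(unique(x)) > 1L)
  if (any(conflict)) {
    stop(ddimage_io_error("duplicate unordered pair with conflicting labels"))
  }
  pairs[!duplicated(key), , drop = FALSE]
}

#' Write a pair table as TSV/CSV
#'
#' @param pairs data.frame with drug_a, drug_b, label.
#' @param path Output path.
#' @export
write_pair_table <- function(pairs, path) {
  utils::write.table(pairs[, c("drug_a", "drug_b", "label")], path,
                     sep = .guess_sep(path), quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Sample non-interacting (negative) drug pairs
#'
#' Draws unordered pairs uniformly without replacement from the complement of
#' the positive set, labelling them 0. Deterministic given `seed`.
#'
#' @param positives Pair data.frame of known interactions.
#' @param drugs Drug table (data.frame with drug_id) or character vector of
#'   drug ids.
#' @param ratio Negatives per positive (default 1).
#' @param seed Integer seed.
#' @return Pair data.frame with label 0, `round(ratio * nrow(positives))`
#'   rows.
#' @export
sample_negatives <- function(positives, drugs, ratio = 1.0, seed = 1L) {
  ids <- if (is.data.frame(drugs)) drugs$drug_id else as.character(drugs)
  ids <- sort(unique(ids))
  n <- length(ids)
  want <- round(ratio * nrow(positives))
  all_pairs <- t(utils::combn(ids, 2L))
  keys <- pair_key(all_pairs[, 1], all_pairs[, 2])
  pos_keys <- pair_key(positives$drug_a, positives$drug_b)
  avail <- which(!keys %in% pos_keys)
  if (length(avail) < want) {
    stop(ddimage_config_error(sprintf(
      "cannot sample %d negatives: only %d non-positive pairs exist among %d drugs",
      want, length(avail), n)))
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  take <- avail[sample.int(length(avail), want)]
  normalize_pairs(data.frame(drug_a = all_pairs[take, 1],
                             drug_b = all_pairs[take, 2],
                             label = 0L, stringsAsFactors = FALSE))
}
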