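#' Construct a Calpha trace
#'
#' A `ca_structure` is the ordered Calpha backbone of one model or fragment:
#' residue names (3-letter codes), residue numbers (with optional insertion
#' codes) and one x/y/z coordinate triple per residue, in Angstrom.
#'
#' @param label text identifier for the model.
#' @param resno integer residue numbers, strictly increasing (within ties
#'   broken by insertion code).
#' @param resnames character vector of 3-letter residue codes.
#' @param xyz numeric matrix, one row per residue, columns x/y/z (Angstrom).
#' @param inscode optional character vector of PDB insertion codes ("" if
#'   none).
#' @return an object of class `ca_structure`.
#' @examples
#' s <- ca_structure("toy", 1:4, rep("ALA", 4),
#'                   cbind(3.8 * (0:3), 0, 0))
#' nresidues(s)
#' @export
ca_structure <- function(label, resno, resnames, xyz, inscode = NULL) {
  xyz <- as.matrix(xyz)
  storage.mode(xyz) <- "double"
  n <- length(resno)
  if (n < 3L)
    stop(data_error(sprintf(
      "ca_structure '%s': at least 3 residues required, got %d", label, n)))
  if (is.null(inscode)) inscode <- rep("", n)
  if (length(resnames) != n || nrow(xyz) != n || ncol(xyz) != 3L ||
      length(inscode) != n)
    stop("ca_structure: field lengths disagree")
  if (!all(is.finite(xyz)))
    stop(data_error(sprintf(
      "ca_structure '%s': non-finite coordinates", label)))
  key <- paste0(resno, inscode)
  ord <- order(resno, inscode)
  if (anyDuplicated(key) || !identical(ord, seq_len(n)))
    stop(data_error(sprintf(
      "ca_structure '%s': residue indices must be strictly increasing",
      label)))
  structure(list(label = as.character(label),
                 resno = as.integer(resno),
                 inscode = as.character(inscode),
                 resnames = as.character(resnames),
                 xyz = unname(xyz)),
            class = "ca_structure")
}

#' Number of residues in a Calpha trace
#' @param x a [ca_structure].
#' @return integer residue count.
#' @export
nresidues <- function(x) {
  stopifnot(inherits(x, "ca_structure"))
  length(x$resno)
}

# residue identity keys used to match residues across models
residue_keys <- function(x) paste0(x$resno, x$inscode)

#' One-letter sequence of a Calpha trace
#'
#' Translates the 3-letter residue codes to a one-letter sequence
#' (unknown codes become "X").
#' @param x a [ca_structure].
#' @return a single character string.
#' @export
ca_sequence <- function(x) {
  stopifnot(inherits(x, "ca_structure"))
  paste(bio3d::aa321(x$resnames), collapse = "")
}

#' @export
print.ca_structure <- function(x, ...) {
  cat(sprintf("Calpha trace '%s': %d residues (%d-%d)\n", x$label,
              nresidues(x), x$resno[1], x$resno[nresidues(x)]))
  invisible(x)
}

#' Construct a model ensemble
#'
#' The set of models built in one modelling run for a single target. All
#' models must have the same number of residues and identical residue
#' numbering; heterogeneity scoring additionally requires at least two
#' models.
#'
#' @param models list of [ca_structure] objects.
#' @return object of class `model_ensemble` with elements `models` and `n`.
#' @export
model_ensemble <- function(models) {
  if (!length(models) || !all(vapply(models, inherits, TRUE, "ca_structure")))
    stop("model_ensemble: need a non-empty list of ca_structure objects")
  keys <- residue_keys(models[[1]])
  for (i in seq_along(models)) {
    if (!identical(residue_keys(models[[i]]), keys))
      stop(data_error(sprintf(
        "model_ensemble: model '%s' (#%d) has a different residue set than model '%s'",
        models[[i]]$label, i, models[[1]]$label)))
  }
  structure(list(models = models, n = length(models)),
            class = "model_ensemble")
}

#' @export
print.model_ensemble <- function(x, ...) {
  cat(sprintf("Model ensemble: n = %d models, %d residues each\n",
              x$n, nresidues(x$models[[1]])))
  invisible(x)
}

#' Construct a target/template pairwise alignment
#'
#' Two gapped rows of equal length N; gap character "-". Columns that are
#' gaps in both rows are not allowed (readers remove them).
#'
#' @param target gapped target sequence (single string).
#' @param template gapped template sequence (single string).
#' @param target_id,template_id row identifiers.
#' @return object of class `pair_alignment` with fields `target`,
#'   `template`, `n` (alignment length).
#' @export
pair_alignment <- function(target, template,
                           target_id = "target", template_id = "template") {
  target <- toupper(gsub(".", "-", target, fixed = TRUE))
  template <- toupper(gsub(".", "-", template, fixed = TRUE))
  if (nchar(target) != nchar(template))
    stop(data_error("pair_alignment: rows have unequal length"))
  tc <- strsplit(target, "")[[1]]
  mc <- strsplit(template, "")[[1]]
  both_gap <- tc == "-" & mc == "-"
  if (any(both_gap)) {
    tc <- tc[!both_gap]
    mc <- mc[!both_gap]
  }
  if (!length(tc))
    stop(data_error("pair_alignment: empty alignment"))
  structure(list(target = paste(tc, collapse = ""),
                 template = paste(mc, collapse = ""),
                 target_id = target_id, template_id = template_id,
                 n = length(tc)),
            class = "pair_alignment")
}

#' @export
print.pair_alignment <- function(x, ...) {
  cat(sprintf("Pairwise alignment %s/%s, N = %d columns\n",
              x$target_id, x$template_id, x$n))
  invisible(x)
}

#' Construct a secondary-structure prediction track
#'
#' Per-residue predicted 3-state secondary structure for the target with
#' integer confidence values. States use the alphabet H (helix), S (strand),
#' C (other). Confidences follow the 1-10 convention by default (raw
#' psipred 0-9 digits are shifted on reading unless disabled).
#'
#' @param states character vector over {H,S,C}, one per target residue.
#' @param conf integer confidences, same length.
#' @return object of class `ss_prediction`.
#' @export
ss_prediction <- function(states, conf) {
  states <- toupper(as.character(states))
  conf <- as.integer(conf)
  if (length(states) != length(conf))
    stop("ss_prediction: states and conf lengths differ")
  bad <- setdiff(unique(states), c("H", "S", "C"))
  if (length(bad))
    stop(data_error(paste0("ss_prediction: unknown state(s): ",
                           paste(bad, collapse = ", "))))
  structure(list(states = states, conf = conf), class = "ss_prediction")
}

#' Construct a secondary-structure assignment track
#'
#' Per-residue observed 3-state secondary structure of the template
#' (typically reduced from a stride or DSSP assignment).
#'
#' @param states character vector over {H,S,C}, one per template residue.
#' @return object of class `ss_assignment`.
#' @export
ss_assignment <- function(states) {
  states <- toupper(as.character(states))
  bad <- setdiff(unique(states), c("H", "S", "C"))
  if (length(bad))
    stop(data_error(paste0("ss_assignment: unknown state(s): ",
                           paste(bad, collapse = ", "))))
  structure(list(states = states), class = "ss_assignment")
}
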