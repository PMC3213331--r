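# Readers/writers for the external formats the metric touches: PDB Calpha
# traces, FASTA/Clustal alignments, psipred predictions, stride/DSSP
# assignments, and the score report.

# Parse the ATOM/MODEL/ENDMDL records of one PDB file into a list of
# per-model atom tables. Fixed-column parsing; HETATM and everything else
# is ignored. Only CA atoms of the requested chain are kept.
parse_pdb_ca <- function(path, chain = NULL) {
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  models <- list()
  cur <- integer(0)
  atom_idx <- which(rec == "ATOM  ")
  is_model <- rec == "MODEL "
  is_endmdl <- rec == "ENDMDL"
  # split atom lines into MODEL blocks; files without MODEL records are a
  # single block
  model_of <- cumsum(is_model)[atom_idx]
  if (!length(atom_idx))
    stop(data_error(sprintf("no ATOM records found in '%s'", path)))
  blocks <- split(lines[atom_idx], model_of)
  lapply(blocks, function(bl) {
    name <- trimws(substr(bl, 13, 16))
    keep <- name == "CA"
    bl <- bl[keep]
    if (!length(bl)) return(NULL)
    ch <- substr(bl, 22, 22)
    use_chain <- chain %||% ch[1]
    bl <- bl[ch == use_chain]
    data.frame(
      altloc = substr(bl, 17, 17),
      resname = trimws(substr(bl, 18, 20)),
      resno = as.integer(substr(bl, 23, 26)),
      inscode = trimws(substr(bl, 27, 27)),
      x = as.numeric(substr(bl, 31, 38)),
      y = as.numeric(substr(bl, 39, 46)),
      z = as.numeric(substr(bl, 47, 54)),
      occ = suppressWarnings(as.numeric(substr(bl, 55, 60))),
      stringsAsFactors = FALSE)
  })
}

# Resolve alternate locations: per residue keep the CA with highest
# occupancy (missing occupancy counts as 1), ties broken by file order.
resolve_altloc <- function(df) {
  df$occ[is.na(df$occ)] <- 1
  key <- paste0(df$resno, df$inscode)
  pick <- tapply(seq_len(nrow(df)), factor(key, levels = unique(key)),
                 function(i) i[which.max(df$occ[i])])
  df[unlist(pick), , drop = FALSE]
}

#' Read a model ensemble from PDB files
#'
#' Reads one or more PDB files -- either a single multi-MODEL file or one
#' file per model -- and returns the Calpha traces as a [model_ensemble].
#' Only `ATOM` records are parsed; `HETATM` is ignored. Alternate locations
#' are resolved to the highest-occupancy conformer (first listed on ties).
#' A residue whose Calpha is missing in any model is dropped from all
#' models, with a warning, so the traces stay in 1:1 correspondence.
#'
#' @param paths character vector of PDB file paths. A single path may
#'   contain multiple `MODEL` blocks.
#' @param chain chain identifier to read; default is the first chain
#'   encountered in each file.
#' @return a [model_ensemble], models in input order.
#' @export
read_ca_models <- function(paths, chain = NULL) {
  tabs <- list()
  for (p in paths) {
    if (!file.exists(p))
      stop(data_error(sprintf("model file '%s' does not exist", p)))
    blocks <- parse_pdb_ca(p, chain = chain)
    base <- sub("\\.(pdb|ent)$", "", basename(p), ignore.case = TRUE)
    for (bi in seq_along(blocks)) {
      b <- blocks[[bi]]
      if (is.null(b)) next
      lab <- if (length(blocks) > 1L) sprintf("%s#%d", base, bi) else base
      tabs[[lab]] <- resolve_altloc(b)
    }
  }
  if (!length(tabs))
    stop(data_error("no Calpha atoms found in the input"))
  keysets <- lapply(tabs, function(d) paste0(d$resno, d$inscode))
  common <- Reduce(intersect, keysets)
  if (length(common) < 3L) {
    # a sporadic missing Calpha is tolerated (dropped below); wholesale
    # residue-set disagreement is an input error naming the offender
    off <- which(!vapply(keysets, identical, TRUE, keysets[[1]]))[1]
    stop(data_error(sprintf(
      "residue sets of the models do not match: model '%s' shares fewer than 3 residues with '%s'",
      names(tabs)[if (is.na(off)) 1L else off], names(tabs)[1])))
  }
  dropped <- setdiff(unique(unlist(keysets)), common)
  if (length(dropped))
    warning(sprintf(
      "residue(s) %s lack a Calpha in at least one model; dropped from all models",
      paste(dropped, collapse = ", ")), call. = FALSE)
  models <- lapply(names(tabs), function(lab) {
    d <- tabs[[lab]]
    d <- d[match(common, paste0(d$resno, d$inscode)), , drop = FALSE]
    ca_structure(lab, d$resno, d$resname,
                 cbind(d$x, d$y, d$z), inscode = d$inscode)
  })
  model_ensemble(models)
}

#' Write a model ensemble as a multi-MODEL PDB file
#'
#' Coordinates are written with the standard PDB 3-decimal precision.
#' Residues are emitted as chain A with the stored numbering.
#'
#' @param ensemble a [model_ensemble] or single [ca_structure].
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_ca_models <- function(ensemble, path) {
  if (inherits(ensemble, "ca_structure"))
    ensemble <- structure(list(models = list(ensemble), n = 1L),
                          class = "model_ensemble")
  con <- file(path, "w")
  on.exit(close(con))
  multi <- ensemble$n > 1L
  for (mi in seq_len(ensemble$n)) {
    m <- ensemble$models[[mi]]
    if (multi) writeLines(sprintf("MODEL     %4d", mi), con)
    for (i in seq_len(nresidues(m))) {
      writeLines(sprintf(
        "ATOM  %5d  CA  %-3s A%4d%1s   %8.3f%8.3f%8.3f  1.00  0.00           C",
        i, m$resnames[i], m$resno[i],
        ifelse(nzchar(m$inscode[i]), m$inscode[i], " "),
        m$xyz[i, 1], m$xyz[i, 2], m$xyz[i, 3]), con)
    }
    if (multi) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Read a target/template alignment
#'
#' Reads a FASTA or Clustal alignment and extracts the two rows named by
#' `target_id` and `template_id` (default: the first two rows). Rows are
#' upper-cased, "." is treated as a gap, and columns that are gaps in both
#' rows are removed.
#'
#' @param path alignment file.
#' @param format "fasta" or "clustal".
#' @param target_id,template_id row identifiers to select; `NULL` picks the
#'   first two rows in file order.
#' @return a [pair_alignment].
#' @export
read_alignment <- function(path, format = c("fasta", "clustal"),
                           target_id = NULL, template_id = NULL) {
  format <- match.arg(format)
  if (!file.exists(path))
    stop(data_error(sprintf("alignment file '%s' does not exist", path)))
  if (format == "fasta") {
    aln <- seqinr::read.alignment(path, format = "fasta",
                                  forceToLower = FALSE)
    nam <- aln$nam
    seqs <- vapply(aln$seq, function(s) as.character(s)[1], "")
    nb <- aln$nb
  } else {
    parsed <- parse_clustal(path)
    nam <- parsed$nam
    seqs <- parsed$seq
    nb <- length(nam)
  }
  pick <- function(id, default_pos) {
    if (is.null(id)) return(default_pos)
    i <- match(id, nam)
    if (is.na(i))
      stop(data_error(sprintf("alignment row '%s' not found in '%s'",
                              id, path)))
    i
  }
  if (nb < 2L)
    stop(data_error("alignment must contain at least two rows"))
  it <- pick(target_id, 1L)
  im <- pick(template_id, if (it == 2L) 1L else 2L)
  if (nchar(seqs[it]) != nchar(seqs[im]))
    stop(data_error("alignment rows have unequal length"))
  pair_alignment(seqs[it], seqs[im],
                 target_id = nam[it], template_id = nam[im])
}

# Minimal Clustal block parser: header line, then blocks of
# "<name> <chunk>" rows with an optional conservation row (leading
# whitespace); chunks are concatenated per name in first-seen order.
parse_clustal <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || !startsWith(lines[1], "CLUSTAL"))
    stop(data_error(sprintf("'%s' is not a Clustal file", path)))
  lines <- lines[-1]
  lines <- lines[nzchar(trimws(lines))]
  lines <- lines[!grepl("^\\s", lines)]        # conservation rows
  m <- regmatches(lines, regexec("^(\\S+)\\s+(\\S+)", lines))
  ok <- lengths(m) == 3L
  if (!any(ok))
    stop(data_error(sprintf("no sequence rows found in '%s'", path)))
  nam_all <- vapply(m[ok], `[`, "", 2L)
  chunk <- vapply(m[ok], `[`, "", 3L)
  chunk <- sub("\\s+\\d+$", "", chunk)         # optional position counter
  nam <- unique(nam_all)
  seqs <- vapply(nam, function(nm)
    paste(chunk[nam_all == nm], collapse = ""), "")
  list(nam = nam, seq = unname(seqs))
}

# map psipred/stride-style letters to the 3-state alphabet used here
map_pred_state <- function(s) {
  out <- c(H = "H", E = "S", S = "S", C = "C")[s]
  if (anyNA(out))
    stop(data_error(paste0("unknown secondary-structure state letter(s): ",
                           paste(unique(s[is.na(out)]), collapse = ", "))))
  unname(out)
}

# integer confidence digit derived from ss2 probabilities; matches the
# digit printed in the horiz dialect for fixture-generated pairs
ss2_conf_digit <- function(pc, ph, pe) {
  p <- cbind(pc, ph, pe)
  srt <- t(apply(p, 1, sort, decreasing = TRUE))
  pmin(9L, as.integer(floor(10 * (srt[, 1] - srt[, 2]))))
}

#' Read a psipred secondary-structure prediction
#'
#' Supports the vertical `ss2` layout (index, residue, state, three
#' probabilities) and the horizontal `horiz` layout (`Conf:`/`Pred:`/`AA:`
#' blocks). States are mapped H to H, E to S, C to C. Raw confidences are
#' the 0-9 digits psipred prints; by default they are shifted by +1 onto
#' the 1-10 convention (disable with `confidence_shift = FALSE`). For the
#' ss2 dialect the digit is derived from the probability columns as
#' `floor(10 * (p_max - p_second))`, capped at 9.
#'
#' @param path prediction file.
#' @param dialect "ss2" or "horiz".
#' @param confidence_shift logical; shift raw 0-9 digits to 1-10.
#' @param target_sequence optional target sequence to check the length
#'   against.
#' @return an [ss_prediction].
#' @export
read_ss_prediction <- function(path, dialect = c("ss2", "horiz"),
                               confidence_shift = TRUE,
                               target_sequence = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path))
    stop(data_error(sprintf("prediction file '%s' does not exist", path)))
  lines <- readLines(path, warn = FALSE)
  if (dialect == "ss2") {
    lines <- trimws(lines)
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    fields <- strsplit(lines, "\\s+")
    ok <- lengths(fields) >= 6L
    if (!any(ok))
      stop(data_error(sprintf("no ss2 data lines in '%s'", path)))
    fields <- fields[ok]
    states <- map_pred_state(vapply(fields, `[`, "", 3L))
    pc <- as.numeric(vapply(fields, `[`, "", 4L))
    ph <- as.numeric(vapply(fields, `[`, "", 5L))
    pe <- as.numeric(vapply(fields, `[`, "", 6L))
    raw <- ss2_conf_digit(pc, ph, pe)
  } else {
    conf <- paste(sub("^\\s*Conf:\\s*", "",
                      grep("^\\s*Conf:", lines, value = TRUE)),
                  collapse = "")
    pred <- paste(sub("^\\s*Pred:\\s*", "",
                      grep("^\\s*Pred:", lines, value = TRUE)),
                  collapse = "")
    conf <- gsub("\\s", "", conf)
    pred <- gsub("\\s", "", pred)
    if (!nzchar(pred))
      stop(data_error(sprintf("no Pred: lines in '%s'", path)))
    if (nchar(conf) != nchar(pred))
      stop(data_error("horiz Conf: and Pred: tracks have unequal length"))
    states <- map_pred_state(strsplit(pred, "")[[1]])
    raw <- as.integer(strsplit(conf, "")[[1]])
  }
  if (!is.null(target_sequence) &&
      length(states) != nchar(gsub("-", "", target_sequence)))
    stop(data_error(sprintf(
      "prediction covers %d residues but the target has %d",
      length(states), nchar(gsub("-", "", target_sequence)))))
  ss_prediction(states, if (confidence_shift) raw + 1L else raw)
}

#' Read a secondary-structure assignment (stride or DSSP)
#'
#' Parses stride `ASG` records or a DSSP output table and reduces the
#' 7/8-state codes to {H,S,C} via [default_reduction_table()] (override
#' with `table`).
#'
#' @param path assignment file.
#' @param dialect "stride" or "dssp".
#' @param table reduction table, see [default_reduction_table()].
#' @return an [ss_assignment].
#' @export
read_ss_assignment <- function(path, dialect = c("stride", "dssp"),
                               table = default_reduction_table()) {
  dialect <- match.arg(dialect)
  if (!file.exists(path))
    stop(data_error(sprintf("assignment file '%s' does not exist", path)))
  lines <- readLines(path, warn = FALSE)
  if (dialect == "stride") {
    asg <- lines[startsWith(lines, "ASG")]
    if (!length(asg))
      stop(data_error(sprintf("no stride ASG records in '%s'", path)))
    codes <- vapply(strsplit(asg, "\\s+"), `[`, "", 6L)
  } else {
    hdr <- grep("^  #  RESIDUE", lines)
    if (!length(hdr))
      stop(data_error(sprintf("no DSSP residue table in '%s'", path)))
    body <- lines[(hdr[1] + 1L):length(lines)]
    body <- body[nchar(body) >= 17]
    body <- body[substr(body, 14, 14) != "!"]   # chain breaks
    if (!length(body))
      stop(data_error(sprintf("no parsable DSSP data lines in '%s'", path)))
    codes <- substr(body, 17, 17)
    codes[codes == "S"] <- " "   # DSSP bend, not strand
  }
  ss_assignment(vapply(codes, reduce_to_three_state, "", table = table,
                       USE.NAMES = FALSE))
}

#' Write an H-factor score report
#'
#' Serialises a [hfactor] breakdown as JSON or TSV. Unavailable component
#' scores are rendered `"n/a"`. Key order is fixed so identical inputs
#' yield byte-identical reports.
#'
#' @param breakdown a [hfactor] object.
#' @param path output path, or `""` for stdout.
#' @param format "json" or "tsv".
#' @return invisibly, `path`.
#' @seealso [read_breakdown()]
#' @export
write_breakdown <- function(breakdown, path, format = c("json", "tsv")) {
  format <- match.arg(format)
  stopifnot(inherits(breakdown, "hfactor"))
  s <- breakdown$scores
  fmt1 <- function(v) if (is.na(v)) "n/a" else sprintf("%.2f", v)
  if (format == "tsv") {
    # column order mirrors the published score tables:
    # target, scores (1)-(4), H-factor (%)
    hdr <- paste(c("target", "score1", "score2", "score3", "score4",
                   "h_factor_percent", "mode"), collapse = "\t")
    row <- paste(c(breakdown$label, vapply(s, fmt1, ""),
                   sprintf("%d", breakdown$h_percent_rounded),
                   breakdown$mode), collapse = "\t")
    out <- c(hdr, row)
  } else {
    obj <- list(
      target = breakdown$label,
      mode = breakdown$mode,
      scores = lapply(s, function(v) if (is.na(v)) "n/a" else v),
      available = as.list(!vapply(s, is.na, TRUE)),
      h_percent = breakdown$h_percent,
      h_percent_rounded = breakdown$h_percent_rounded,
      ensemble_spread = breakdown$spread,
      config = unclass(breakdown$config),
      provenance = breakdown$provenance
    )
    out <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA,
                            null = "null", pretty = TRUE)
  }
  if (identical(path, "")) {
    cat(out, sep = "\n")
  } else {
    ok <- tryCatch({ writeLines(out, path); TRUE },
                   error = function(e) FALSE)
    if (!ok) stop(data_error(sprintf("cannot write report to '%s'", path)))
  }
  invisible(path)
}

#' Read back a JSON score report
#'
#' Inverse of [write_breakdown()] for the JSON format; returns a [hfactor]
#' object carrying the stored scores and aggregate.
#'
#' @param path JSON report written by [write_breakdown()].
#' @return a [hfactor] object.
#' @export
read_breakdown <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  s <- lapply(obj$scores, function(v) if (identical(v, "n/a")) NA_real_ else
    as.numeric(v))
  cfg <- do.call(hfactor_config, obj$config)
  new_hfactor(scores = s, mode = obj$mode, config = cfg,
              label = obj$target, spread = obj$ensemble_spread,
              provenance = obj$provenance)
}
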