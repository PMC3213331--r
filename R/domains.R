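# Domain bookkeeping for the domain-consistency score: HMMER domain-table
# parsing, fragment extraction from the average model, and
# alignment-mediated cRMS against reference domain structures.

#' Construct a domain hit
#'
#' A profile-HMM match on the target sequence: domain accession, 1-based
#' inclusive start/end positions (envelope coordinates), and E-value.
#'
#' @param domain_id accession/name of the matched profile (e.g. a Pfam id).
#' @param start,end 1-based inclusive residue positions on the target.
#' @param e_value reported per-domain independent E-value.
#' @return object of class `domain_hit`.
#' @export
domain_hit <- function(domain_id, start, end, e_value) {
  start <- as.integer(start); end <- as.integer(end)
  if (is.na(start) || is.na(end) || start < 1L || end < start)
    stop(data_error(sprintf("domain_hit %s: invalid span %s-%s",
                            domain_id, start, end)))
  if (is.na(e_value) || e_value < 0)
    stop(data_error(sprintf("domain_hit %s: invalid E-value", domain_id)))
  structure(list(domain_id = as.character(domain_id), start = start,
                 end = end, e_value = as.numeric(e_value)),
            class = "domain_hit")
}

#' Parse an HMMER3 domain table
#'
#' Reads a `hmmsearch --domtblout` file, keeps hits whose per-domain
#' independent E-value (column 13) is at or below `cfg$evalue_cutoff`,
#' sorts ascending by E-value (ties keep file order) and truncates to
#' `cfg$max_fragments` hits. Envelope coordinates (columns 20/21) define
#' the hit span on the target sequence. Malformed lines are skipped with a
#' warning.
#'
#' @param path domain-table file.
#' @param cfg an [hfactor_config] supplying `evalue_cutoff` and
#'   `max_fragments`.
#' @return list of [domain_hit] objects (possibly empty, in which case the
#'   domain score is unavailable).
#' @export
parse_hmmsearch_domtbl <- function(path, cfg = hfactor_config()) {
  if (!file.exists(path))
    stop(data_error(sprintf("domain table '%s' does not exist", path)))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
  hits <- list()
  for (ln in lines) {
    f <- strsplit(trimws(ln), "\\s+")[[1]]
    h <- if (length(f) >= 22L) tryCatch(
      domain_hit(domain_id = f[4],
                 start = f[20], end = f[21],
                 e_value = suppressWarnings(as.numeric(f[13]))),
      error = function(e) NULL) else NULL
    if (is.null(h)) {
      warning(sprintf("skipping malformed domtbl line: %.60s", ln),
              call. = FALSE)
      next
    }
    hits[[length(hits) + 1L]] <- h
  }
  ev <- vapply(hits, `[[`, 0, "e_value")
  hits <- hits[ev <= cfg$evalue_cutoff]
  ev <- ev[ev <= cfg$evalue_cutoff]
  hits <- hits[order(ev)]             # stable: ties keep file order
  utils::head(hits, cfg$max_fragments)
}

#' Extract a domain fragment from a Calpha trace
#'
#' Returns the contiguous sub-trace covering positions `hit$start` to
#' `hit$end` (1-based inclusive positions along the chain, i.e. the i-th
#' residue, not PDB numbering).
#'
#' @param ma an [average_model] or [ca_structure].
#' @param hit a [domain_hit].
#' @return a [ca_structure] fragment.
#' @export
extract_fragment <- function(ma, hit) {
  struct <- if (inherits(ma, "average_model")) ma$structure else ma
  stopifnot(inherits(struct, "ca_structure"), inherits(hit, "domain_hit"))
  n <- nresidues(struct)
  if (hit$end > n)
    stop(data_error(sprintf(
      "domain %s span %d-%d exceeds the %d-residue model",
      hit$domain_id, hit$start, hit$end, n)))
  idx <- hit$start:hit$end
  ca_structure(sprintf("%s:%d-%d", hit$domain_id, hit$start, hit$end),
               struct$resno[idx], struct$resnames[idx],
               struct$xyz[idx, , drop = FALSE],
               inscode = struct$inscode[idx])
}

#' Alignment-mediated cRMS between two domain structures
#'
#' Pairs the Calpha atoms of two fragments of (possibly) different
#' sequences via a global Needleman-Wunsch alignment (BLOSUM62, affine
#' gaps: opening 10, extension 0.5) and returns the Kabsch-fit RMSD over
#' the aligned pairs. Returns `NA` when fewer than 3 positions align
#' (the caller skips such pairs).
#'
#' @param a,b [ca_structure] fragments.
#' @param seq_a,seq_b their one-letter sequences; derived from the residue
#'   names when omitted.
#' @return cRMS in Angstrom, or `NA_real_` if fewer than 3 pairs align.
#' @export
domain_crms <- function(a, b, seq_a = ca_sequence(a),
                        seq_b = ca_sequence(b)) {
  stopifnot(inherits(a, "ca_structure"), inherits(b, "ca_structure"))
  if (nchar(seq_a) != nresidues(a) || nchar(seq_b) != nresidues(b))
    stop(data_error("sequence length does not match the structure"))
  pa <- Biostrings::pairwiseAlignment(
    seq_a, seq_b, type = "global",
    substitutionMatrix = blosum62_matrix(),
    gapOpening = 10, gapExtension = 0.5)
  arow <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  brow <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  ai <- cumsum(arow != "-")
  bi <- cumsum(brow != "-")
  paired <- arow != "-" & brow != "-"
  if (sum(paired) < 3L) return(NA_real_)
  crms(a$xyz[ai[paired], , drop = FALSE],
       b$xyz[bi[paired], , drop = FALSE])
}

# BLOSUM62 from Biostrings, loaded once per session
blosum62_env <- new.env(parent = emptyenv())
blosum62_matrix <- function() {
  if (is.null(blosum62_env$m)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    blosum62_env$m <- e$BLOSUM62
  }
  blosum62_env$m
}

#' Construct a domain reference set
#'
#' @param refs named list: domain id to list of references, each a list
#'   with elements `structure` (a [ca_structure]) and `sequence`
#'   (one-letter string).
#' @return object of class `domain_reference_set` (a named list).
#' @export
domain_reference_set <- function(refs) {
  for (id in names(refs)) for (r in refs[[id]]) {
    if (!inherits(r$structure, "ca_structure") || nresidues(r$structure) < 3L)
      stop(data_error(sprintf(
        "reference for domain %s must be a ca_structure with >= 3 residues",
        id)))
  }
  structure(refs, class = "domain_reference_set")
}

#' Read reference domain structures from a manifest
#'
#' The manifest is a JSON object mapping each domain id to a list of
#' references `{file, chain, sequence}`; `file` is a PDB path relative to
#' the manifest, `sequence` (optional) overrides the sequence derived from
#' the residue names.
#'
#' @param manifest_path path to the JSON manifest.
#' @return a `domain_reference_set`.
#' @export
read_domain_refs <- function(manifest_path) {
  if (!file.exists(manifest_path))
    stop(data_error(sprintf("manifest '%s' does not exist", manifest_path)))
  man <- jsonlite::fromJSON(manifest_path, simplifyVector = FALSE)
  base <- dirname(manifest_path)
  refs <- lapply(man, function(entries) lapply(entries, function(e) {
    p <- e$file
    if (!file.exists(p)) p <- file.path(base, e$file)
    ens <- read_ca_models(p, chain = e$chain %||% NULL)
    st <- ens$models[[1]]
    list(structure = st, sequence = e$sequence %||% ca_sequence(st))
  }))
  domain_reference_set(refs)
}

#' Run hmmsearch against a profile database (optional adapter)
#'
#' Thin wrapper over an external `hmmsearch` binary: writes the target
#' sequence to a temporary FASTA, runs
#' `hmmsearch --domtblout <out> <profile_db> <fasta>` and returns the
#' domain-table path for [parse_hmmsearch_domtbl()]. Purely optional --
#' precomputed domain tables can always be supplied instead.
#'
#' @param target_sequence one-letter target sequence.
#' @param profile_db path to a profile database (e.g. Pfam HMMs).
#' @param out output domain-table path.
#' @param hmmsearch path/name of the hmmsearch executable.
#' @return `out`, invisibly.
#' @export
run_hmmsearch_adapter <- function(target_sequence, profile_db,
                                  out = tempfile(fileext = ".domtbl"),
                                  hmmsearch = "hmmsearch") {
  bin <- Sys.which(hmmsearch)
  if (!nzchar(bin))
    stop(data_error(paste0(
      "hmmsearch executable not found on PATH; run the search elsewhere ",
      "and supply its --domtblout file via parse_hmmsearch_domtbl()")))
  fa <- tempfile(fileext = ".fasta")
  on.exit(unlink(fa))
  writeLines(c(">target", target_sequence), fa)
  status <- system2(bin, c("--domtblout", shQuote(out),
                           shQuote(profile_db), shQuote(fa)),
                    stdout = FALSE, stderr = FALSE)
  if (status != 0L || !file.exists(out))
    stop(data_error(sprintf("hmmsearch failed with status %d", status)))
  invisible(out)
}
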