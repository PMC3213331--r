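# Deterministic synthetic-data generator: every input the metric consumes
# can be produced at toy scale with known ground truth, so all scores are
# testable offline. Every generator is a pure function of its spec.

AA1 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
         "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Specification for the synthetic-fixture generators
#'
#' @param seed integer RNG seed; the same spec always produces identical
#'   fixtures.
#' @param n_models models per ensemble (>= 2); default 20, the ensemble
#'   size used throughout the validation protocol.
#' @param n_residues chain/alignment length (>= 5).
#' @param target_spread intended ensemble spread (mean cRMS to the average
#'   model) in Angstrom; the generator calibrates its noise so the
#'   realised spread lands within 15% of this.
#' @param identity_fraction fraction of alignment columns that are
#'   identical residue pairs.
#' @param gap_fraction fraction of alignment columns carrying a gap.
#' @param ss_agreement fraction of aligned residue pairs whose predicted
#'   and observed secondary-structure states agree.
#' @param confidence integer prediction-confidence profile on the 1-10
#'   scale, sampled per residue.
#' @return object of class `fixture_spec`.
#' @export
fixture_spec <- function(seed, n_models = 20L, n_residues = 60L,
                         target_spread = 1.0, identity_fraction = 0.5,
                         gap_fraction = 0, ss_agreement = 0.8,
                         confidence = 1:10) {
  spec <- list(seed = as.integer(seed), n_models = as.integer(n_models),
               n_residues = as.integer(n_residues),
               target_spread = as.numeric(target_spread),
               identity_fraction = as.numeric(identity_fraction),
               gap_fraction = as.numeric(gap_fraction),
               ss_agreement = as.numeric(ss_agreement),
               confidence = as.integer(confidence))
  with(spec, {
    stopifnot(n_models >= 2L, n_residues >= 5L, target_spread >= 0,
              identity_fraction >= 0, identity_fraction <= 1,
              gap_fraction >= 0, gap_fraction <= 1,
              ss_agreement >= 0, ss_agreement <= 1,
              all(confidence >= 1L), all(confidence <= 10L))
  })
  structure(spec, class = "fixture_spec")
}

# smooth self-avoiding 3D walk with 3.8 A Calpha steps; non-neighbour
# contacts closer than 2.5 A are rejected (loose self-avoidance only)
make_chain_xyz <- function(n) {
  x <- matrix(0, n, 3)
  dir <- c(1, 0, 0)
  for (i in 2:n) {
    for (try in 1:50) {
      wob <- if (try <= 25) 0.45 else 1.5   # loosen if stuck
      cand <- dir + stats::rnorm(3, sd = wob)
      cand <- cand / sqrt(sum(cand^2))
      p <- x[i - 1, ] + 3.8 * cand
      if (i <= 3) break
      dmin <- min(sqrt(rowSums(sweep(x[1:(i - 2), , drop = FALSE], 2, p)^2)))
      if (dmin >= 2.5) break
    }
    dir <- cand
    x[i, ] <- p
  }
  x
}

random_rotation <- function() {
  q <- qr(matrix(stats::rnorm(9), 3))
  r <- qr.Q(q) %*% diag(sign(diag(qr.R(q))))
  if (det(r) < 0) r[, 1] <- -r[, 1]
  r
}

# project a displacement field orthogonal to the 6 rigid-body modes of x
# (3 translations + 3 infinitesimal rotations), so that for moderate
# amplitudes the Kabsch fit of x vs x+v stays at the identity and the
# realised cRMS equals the RMS amplitude of v
project_out_rigid <- function(v, x) {
  n <- nrow(x)
  xc <- sweep(x, 2, colMeans(x))
  basis <- matrix(0, 3 * n, 6)
  for (k in 1:3) {
    tmode <- matrix(0, n, 3); tmode[, k] <- 1
    e <- c(0, 0, 0); e[k] <- 1
    rmode <- t(apply(xc, 1, function(p) c(e[2] * p[3] - e[3] * p[2],
                                          e[3] * p[1] - e[1] * p[3],
                                          e[1] * p[2] - e[2] * p[1])))
    basis[, k] <- as.vector(tmode)
    basis[, 3 + k] <- as.vector(rmode)
  }
  q <- qr.Q(qr(basis))
  vf <- as.vector(v)
  matrix(vf - q %*% crossprod(q, vf), n, 3)
}

#' Generate a synthetic model ensemble with a planted spread
#'
#' Builds a base Calpha chain as a smooth self-avoiding walk, adds iid
#' Gaussian perturbations to produce each model, and rescales the noise
#' (measuring the realised spread with the real superposition engine)
#' until the ensemble spread is within 15% of `target_spread`; each model
#' then receives an independent random rigid motion, which the spread is
#' invariant to. `target_spread = 0` yields exact copies.
#'
#' @param spec a [fixture_spec].
#' @param sequence optional one-letter sequence for the residue names
#'   (defaults to a random sequence of length `n_residues`).
#' @return list with `ensemble` (a [model_ensemble]), `realised_spread`,
#'   `base` (the noise-free [ca_structure]), and `spec`.
#' @export
make_ensemble <- function(spec, sequence = NULL) {
  stopifnot(inherits(spec, "fixture_spec"))
  with_seed(spec$seed, {
    n <- spec$n_residues
    seq1 <- if (is.null(sequence)) paste(sample(AA1, n, replace = TRUE),
                                         collapse = "") else sequence
    stopifnot(nchar(seq1) == n)
    resnames <- bio3d::aa123(strsplit(seq1, "")[[1]])
    xyz <- make_chain_xyz(n)
    base <- ca_structure("base", seq_len(n), resnames, xyz)
    dev <- lapply(seq_len(spec$n_models), function(i)
      matrix(stats::rnorm(3 * n), n, 3))
    build <- function(s) model_ensemble(lapply(seq_len(spec$n_models),
      function(i) ca_structure(sprintf("model_%02d", i), seq_len(n),
                               resnames, xyz + s * dev[[i]])))
    if (spec$target_spread == 0) {
      ens <- build(0)
      realised <- 0
    } else {
      s <- spec$target_spread          # initial guess; spread ~ linear in s
      for (pass in 1:3) {
        realised <- ensemble_spread(build(s))
        s <- s * spec$target_spread / realised
      }
      ens <- build(s)
      realised <- ensemble_spread(ens)
    }
    # independent rigid motion per model; superposition removes it
    moved <- lapply(ens$models, function(m) {
      m$xyz <- sweep(m$xyz %*% random_rotation(), 2,
                     stats::rnorm(3, sd = 20), `+`)
      m
    })
    list(ensemble = model_ensemble(moved), realised_spread = realised,
         base = base, spec = spec)
  })
}

#' Generate a synthetic target/template alignment with planted identity
#'
#' The number of identical columns is exactly
#' `round(identity_fraction * N)` and the number of gap-bearing columns
#' exactly `round(gap_fraction * N)` (gaps alternate between the target
#' and template rows), so the identity score of the result is known in
#' closed form.
#'
#' @param spec a [fixture_spec]; `n_residues` is the alignment length N.
#' @return a [pair_alignment] with attributes `planted_identity`,
#'   `n_gap_columns`, and `expected_score2`.
#' @export
make_alignment <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  with_seed(spec$seed + 1L, {
    n <- spec$n_residues
    n_id <- round(spec$identity_fraction * n)
    n_gap <- round(spec$gap_fraction * n)
    if (n_id + n_gap > n)
      stop(data_error("identity_fraction + gap_fraction exceed 1"))
    type <- rep("mismatch", n)
    pick <- sample.int(n, n_id + n_gap)
    type[pick[seq_len(n_id)]] <- "identity"
    if (n_gap) type[pick[n_id + seq_len(n_gap)]] <- "gap"
    tc <- mc <- character(n)
    gap_in_target <- TRUE
    for (i in seq_len(n)) {
      if (type[i] == "identity") {
        tc[i] <- mc[i] <- sample(AA1, 1)
      } else if (type[i] == "mismatch") {
        p <- sample(AA1, 2)
        tc[i] <- p[1]; mc[i] <- p[2]
      } else {
        if (gap_in_target) { tc[i] <- "-"; mc[i] <- sample(AA1, 1) }
        else { tc[i] <- sample(AA1, 1); mc[i] <- "-" }
        gap_in_target <- !gap_in_target
      }
    }
    aln <- pair_alignment(paste(tc, collapse = ""),
                          paste(mc, collapse = ""))
    attr(aln, "planted_identity") <- n_id
    attr(aln, "n_gap_columns") <- n_gap
    attr(aln, "expected_score2") <- 10 * (1 - n_id / n)
    aln
  })
}

#' Generate a matched prediction/assignment pair with planted agreement
#'
#' Draws an observed 3-state track for the template, copies it onto the
#' aligned target positions, then flips exactly
#' `round((1 - ss_agreement) * n_paired)` of the paired positions to a
#' different state. With the per-column penalties of the
#' secondary-structure score this makes the expected score-1 value exact
#' in closed form, stored as an attribute.
#'
#' @param spec a [fixture_spec].
#' @param aln a [pair_alignment] providing the column structure; by
#'   default an ungapped 1:1 alignment of length `n_residues`.
#' @param cfg an [hfactor_config] used for the closed-form expectation.
#' @return list with `pred` ([ss_prediction]), `obs` ([ss_assignment]),
#'   `expected_score1`, and `n_flipped`.
#' @export
make_ss_pair <- function(spec, aln = NULL, cfg = hfactor_config()) {
  stopifnot(inherits(spec, "fixture_spec"))
  with_seed(spec$seed + 2L, {
    if (is.null(aln)) {
      s <- paste(sample(AA1, spec$n_residues, replace = TRUE), collapse = "")
      aln <- pair_alignment(s, s)
    }
    tc <- strsplit(aln$target, "")[[1]]
    mc <- strsplit(aln$template, "")[[1]]
    nt <- sum(tc != "-"); nm <- sum(mc != "-")
    obs <- sample(c("H", "S", "C"), nm, replace = TRUE)
    pred <- sample(c("H", "S", "C"), nt, replace = TRUE)
    conf <- spec$confidence[sample.int(length(spec$confidence), nt,
                                       replace = TRUE)]
    # indices of target residues aligned to a template residue
    ti <- cumsum(tc != "-")
    mi <- cumsum(mc != "-")
    paired_cols <- which(tc != "-" & mc != "-")
    pred[ti[paired_cols]] <- obs[mi[paired_cols]]
    k <- round((1 - spec$ss_agreement) * length(paired_cols))
    flip_cols <- if (k) sample(paired_cols, k) else integer(0)
    for (cc in flip_cols) {
      cur <- pred[ti[cc]]
      pred[ti[cc]] <- sample(setdiff(c("H", "S", "C"), cur), 1)
    }
    n_gapcols <- aln$n - length(paired_cols)
    penalty <- n_gapcols + sum(conf[ti[flip_cols]] + 1)
    expected <- cfg$a1 * penalty / aln$n + cfg$b1
    if (cfg$clamp) expected <- max(0, min(10, expected))
    list(pred = ss_prediction(pred, conf), obs = ss_assignment(obs),
         expected_score1 = expected, n_flipped = k, alignment = aln)
  })
}

#' Generate a synthetic domain-comparison case with a planted cRMS
#'
#' Builds a target chain, plants one domain hit on it, and constructs
#' reference structures equal to the corresponding fragment plus a noise
#' field that is (i) projected orthogonal to the rigid-body modes and
#' (ii) rescaled once against the real [domain_crms()] oracle, so the
#' realised alignment-mediated cRMS matches `rmsd` very closely (well
#' within 10%). `rmsd = 0` yields exact copies.
#'
#' @param spec a [fixture_spec]; `n_residues` sets the chain length.
#' @param rmsd target alignment-mediated cRMS in Angstrom.
#' @param n_refs number of reference structures for the domain.
#' @param dir optional directory; when given, the hit table
#'   (`domains.domtbl`), manifest (`domain_refs.json`) and reference PDB
#'   files are written there in their standard dialects.
#' @param cfg an [hfactor_config] used for the closed-form expected score.
#' @return list with `ma` (the target [ca_structure]), `hits`, `refs`,
#'   `realised_crms` (per reference), and `expected_score4`.
#' @export
make_domain_case <- function(spec, rmsd, n_refs = 1L, dir = NULL,
                             cfg = hfactor_config()) {
  stopifnot(inherits(spec, "fixture_spec"), rmsd >= 0)
  with_seed(spec$seed + 3L, {
    n <- spec$n_residues
    seq1 <- paste(sample(AA1, n, replace = TRUE), collapse = "")
    ma <- ca_structure("target_avg", seq_len(n),
                       bio3d::aa123(strsplit(seq1, "")[[1]]),
                       make_chain_xyz(n))
    dlen <- max(5L, n - 4L)
    hit <- domain_hit("PF90001.1", 3L, 2L + dlen, 1e-20)
    frag <- extract_fragment(ma, hit)
    refs <- lapply(seq_len(n_refs), function(i) {
      st <- frag
      st$label <- sprintf("ref_%s_%d", hit$domain_id, i)
      if (rmsd > 0) {
        v <- project_out_rigid(matrix(stats::rnorm(3 * nresidues(frag)),
                                      ncol = 3), frag$xyz)
        v <- v * rmsd / sqrt(mean(rowSums(v^2)))
        st$xyz <- frag$xyz + v
        measured <- domain_crms(frag, st)
        v <- v * rmsd / measured       # one rescale against the oracle
        st$xyz <- frag$xyz + v
      }
      list(structure = st, sequence = ca_sequence(st))
    })
    refset <- domain_reference_set(stats::setNames(list(refs),
                                                   hit$domain_id))
    realised <- vapply(refs, function(r)
      domain_crms(frag, r$structure), 0)
    expected <- cfg$a4 * mean(realised) + cfg$b4
    if (cfg$clamp) expected <- max(0, min(10, expected))
    if (!is.null(dir)) {
      dir.create(dir, showWarnings = FALSE, recursive = TRUE)
      write_domtbl(list(hit), file.path(dir, "domains.domtbl"),
                   target_len = n)
      man <- stats::setNames(list(lapply(seq_along(refs), function(i) {
        f <- sprintf("%s.pdb", refs[[i]]$structure$label)
        write_ca_models(refs[[i]]$structure, file.path(dir, f))
        list(file = f, chain = "A", sequence = refs[[i]]$sequence)
      })), hit$domain_id)
      jsonlite::write_json(man, file.path(dir, "domain_refs.json"),
                           auto_unbox = TRUE, pretty = TRUE)
    }
    list(ma = ma, hits = list(hit), refs = refset,
         realised_crms = realised, expected_score4 = expected)
  })
}

#' Write domain hits as an HMMER3-style domain table
#'
#' Emits one `--domtblout`-layout line per hit so the planted hits can be
#' round-tripped through [parse_hmmsearch_domtbl()].
#'
#' @param hits list of [domain_hit] objects.
#' @param path output file.
#' @param target_len target sequence length (column 3).
#' @param target_name target sequence name (column 1).
#' @return invisibly, `path`.
#' @export
write_domtbl <- function(hits, path, target_len = 100L,
                         target_name = "target") {
  hdr <- c(
    "#                                                               --- full sequence --- -------------- this domain -------------   hmm coord   ali coord   env coord",
    "# target name        accession   tlen query name           accession   qlen   E-value  score  bias   #  of  c-Evalue  i-Evalue  score  bias  from    to  from    to  from    to  acc description of target",
    "#------------------- ----------         -------------------- ---------- -----   ------- ------ ----- --- ---  --------- --------- ------ ----- ----- ----- ----- ----- ----- ----- ---- ---------------------")
  lines <- vapply(hits, function(h) sprintf(
    "%-20s %-10s %5d %-20s %-10s %5d %.8e %6.1f %5.1f %3d %3d %.8e %.8e %6.1f %5.1f %5d %5d %5d %5d %5d %5d %4.2f synthetic fixture hit",
    target_name, "-", target_len, h$domain_id, "-", h$end - h$start + 1L,
    h$e_value, 100.0, 0.1, 1L, 1L, h$e_value, h$e_value, 100.0, 0.1,
    1L, h$end - h$start + 1L, h$start, h$end, h$start, h$end, 0.95), "")
  writeLines(c(hdr, lines, "#"), path)
  invisible(path)
}

# psipred-style writers used by the bundle generator -------------------

# ss2 probabilities constructed to invert the conf-digit derivation
write_ss2 <- function(pred, path, sequence, confidence_shift = TRUE) {
  raw <- if (confidence_shift) pred$conf - 1L else pred$conf
  stopifnot(all(raw >= 0L), all(raw <= 9L))
  aa <- strsplit(sequence, "")[[1]]
  state_letter <- c(H = "H", S = "E", C = "C")[pred$states]
  p1 <- (raw / 10 + 0.55) / 1.5
  p2 <- (1 - p1) / 2
  probs <- matrix(rep(p2, 3), ncol = 3)   # order: C H E
  col <- c(C = 1L, H = 2L, E = 3L)[state_letter]
  probs[cbind(seq_along(col), col)] <- p1
  lines <- sprintf("%4d %s %s   %.3f  %.3f  %.3f",
                   seq_along(aa), aa, state_letter,
                   probs[, 1], probs[, 2], probs[, 3])
  writeLines(c("# PSF HEADER (synthetic prediction, vertical layout)", "",
               lines), path)
  invisible(path)
}

write_horiz <- function(pred, path, sequence, confidence_shift = TRUE,
                        width = 60L) {
  raw <- if (confidence_shift) pred$conf - 1L else pred$conf
  stopifnot(all(raw >= 0L), all(raw <= 9L))
  state_letter <- c(H = "H", S = "E", C = "C")[pred$states]
  n <- length(raw)
  out <- character(0)
  for (st in seq(1, n, by = width)) {
    en <- min(st + width - 1L, n)
    out <- c(out,
             paste0("Conf: ", paste(raw[st:en], collapse = "")),
             paste0("Pred: ", paste(state_letter[st:en], collapse = "")),
             paste0("  AA: ", substr(sequence, st, en)),
             "")
  }
  writeLines(out, path)
  invisible(path)
}

write_stride <- function(obs, path, sequence) {
  aa3 <- bio3d::aa123(strsplit(sequence, "")[[1]])
  code <- c(H = "H", S = "E", C = "C")[obs$states]
  full <- c(H = "AlphaHelix", E = "Strand", C = "Coil")[code]
  lines <- sprintf("ASG  %-3s A %4d %4d    %s    %-11s   360.00    126.49     120.7      ~~~~",
                   aa3, seq_along(code), seq_along(code), code, full)
  writeLines(c("REM  --------------- Secondary structure summary (synthetic) ---------------",
               lines), path)
  invisible(path)
}

write_clustal <- function(aln, path, width = 60L) {
  out <- c("CLUSTAL W (1.83) multiple sequence alignment", "")
  n <- aln$n
  tc <- strsplit(aln$target, "")[[1]]
  mc <- strsplit(aln$template, "")[[1]]
  cons <- ifelse(tc == mc & tc != "-", "*", " ")
  for (st in seq(1, n, by = width)) {
    en <- min(st + width - 1L, n)
    out <- c(out,
             sprintf("%-16s %s", aln$target_id, substr(aln$target, st, en)),
             sprintf("%-16s %s", aln$template_id, substr(aln$template, st, en)),
             sprintf("%-16s %s", "", paste(cons[st:en], collapse = "")),
             "")
  }
  writeLines(out, path)
  invisible(path)
}

#' Generate a complete synthetic input bundle
#'
#' Writes every file the scorer reads -- a multi-MODEL PDB ensemble, the
#' target/template alignment in both FASTA and Clustal dialects, the
#' secondary-structure prediction in both ss2 and horiz dialects, a
#' stride-style template assignment, an HMMER domain table, and the domain
#' reference manifest -- all generated from one [fixture_spec], plus a
#' `truth.json` recording the planted parameters and closed-form expected
#' scores.
#'
#' @param spec a [fixture_spec].
#' @param dir output directory (created if needed).
#' @param domain_rmsd planted domain cRMS for the reference structures.
#' @return invisibly, a list of the written paths and the ground truth.
#' @export
make_fixture_bundle <- function(spec, dir, domain_rmsd = 1.5) {
  stopifnot(inherits(spec, "fixture_spec"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  aln <- make_alignment(spec)
  target_seq <- gsub("-", "", aln$target)
  template_seq <- gsub("-", "", aln$template)
  ssp <- make_ss_pair(spec, aln = aln)
  spec_chain <- spec
  spec_chain$n_residues <- nchar(target_seq)
  ens <- make_ensemble(spec_chain, sequence = target_seq)
  dom <- with_seed(spec$seed + 4L, {
    dlen <- max(5L, nchar(target_seq) - 4L)
    hit <- domain_hit("PF90001.1", 3L, 2L + dlen, 1e-20)
    frag <- extract_fragment(ens$base, hit)
    ref <- frag
    ref$label <- "ref_PF90001.1_1"
    if (domain_rmsd > 0) {
      v <- project_out_rigid(matrix(stats::rnorm(3 * nresidues(frag)),
                                    ncol = 3), frag$xyz)
      v <- v * domain_rmsd / sqrt(mean(rowSums(v^2)))
      ref$xyz <- frag$xyz + v
      v <- v * domain_rmsd / domain_crms(frag, ref)
      ref$xyz <- frag$xyz + v
    }
    list(hit = hit, ref = ref)
  })
  paths <- list(
    models = file.path(dir, "models.pdb"),
    fasta = file.path(dir, "alignment.fasta"),
    clustal = file.path(dir, "alignment.aln"),
    ss2 = file.path(dir, "target.ss2"),
    horiz = file.path(dir, "target.horiz"),
    stride = file.path(dir, "template.stride"),
    domtbl = file.path(dir, "domains.domtbl"),
    manifest = file.path(dir, "domain_refs.json"),
    truth = file.path(dir, "truth.json"))
  write_ca_models(ens$ensemble, paths$models)
  writeLines(c(">target", aln$target, ">template", aln$template),
             paths$fasta)
  write_clustal(aln, paths$clustal)
  write_ss2(ssp$pred, paths$ss2, target_seq)
  write_horiz(ssp$pred, paths$horiz, target_seq)
  write_stride(ssp$obs, paths$stride, template_seq)
  write_domtbl(list(dom$hit), paths$domtbl,
               target_len = nchar(target_seq))
  reffile <- paste0(dom$ref$label, ".pdb")
  write_ca_models(dom$ref, file.path(dir, reffile))
  jsonlite::write_json(
    stats::setNames(list(list(list(file = reffile, chain = "A",
                                   sequence = ca_sequence(dom$ref)))),
                    dom$hit$domain_id),
    paths$manifest, auto_unbox = TRUE, pretty = TRUE)
  truth <- list(spec = unclass(spec),
                expected_score1 = ssp$expected_score1,
                expected_score2 = attr(aln, "expected_score2"),
                realised_spread = ens$realised_spread,
                domain_rmsd = domain_rmsd)
  jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(paths, list(truth_values = truth)))
}
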