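# The four component scores and their aggregation -- the core of the
# metric. Each score maps its raw statistic onto [0,10] (0 best, 10 worst)
# by an affine transform with fixed offsets; the aggregate is the mean of
# the available scores expressed as a percentage.

#' H-factor configuration
#'
#' Collects every tunable of the metric. The affine offsets are the
#' published calibration: for the secondary-structure score a1 = 1.3,
#' b1 = 0.9; for the heterogeneity and domain scores a = 1.3 and b = 0.87,
#' chosen so that average cRMS values of 0.1 and 7 Angstrom map to scores
#' of 1 and 10.
#'
#' @param a1,b1 slope/offset of the secondary-structure agreement score.
#' @param a3,b3 slope/offset of the ensemble-heterogeneity score
#'   (per-Angstrom slope and offset).
#' @param a4,b4 slope/offset of the domain-consistency score.
#' @param clamp clamp every component score into [0,10] (the offsets only
#'   approximately enforce the range; e.g. 1.3 * 8 + 0.87 > 10).
#' @param evalue_cutoff E-value cutoff applied to HMMER domain hits.
#' @param max_fragments maximum number of domain fragments scored (the
#'   top hits by E-value).
#' @param confidence_shift shift raw psipred 0-9 confidence digits onto
#'   the 1-10 convention when reading predictions.
#' @return object of class `hfactor_config`.
#' @export
hfactor_config <- function(a1 = 1.3, b1 = 0.9,
                           a3 = 1.3, b3 = 0.87,
                           a4 = 1.3, b4 = 0.87,
                           clamp = TRUE,
                           evalue_cutoff = 1.0e-10,
                           max_fragments = 5L,
                           confidence_shift = TRUE) {
  cfg <- list(a1 = as.numeric(a1), b1 = as.numeric(b1),
              a3 = as.numeric(a3), b3 = as.numeric(b3),
              a4 = as.numeric(a4), b4 = as.numeric(b4),
              clamp = isTRUE(clamp),
              evalue_cutoff = as.numeric(evalue_cutoff),
              max_fragments = as.integer(max_fragments),
              confidence_shift = isTRUE(confidence_shift))
  num <- unlist(cfg[c("a1", "b1", "a3", "b3", "a4", "b4", "evalue_cutoff")])
  if (!all(is.finite(num)))
    stop("hfactor_config: coefficients must be finite")
  if (cfg$evalue_cutoff <= 0) stop("hfactor_config: evalue_cutoff must be > 0")
  if (cfg$max_fragments < 1L) stop("hfactor_config: max_fragments must be >= 1")
  structure(cfg, class = "hfactor_config")
}

#' Read an H-factor configuration file
#'
#' Accepts either JSON or simple `key = value` lines (comments with `#`).
#' Unknown keys are an error; missing keys take their defaults.
#'
#' @param path config file.
#' @return an `hfactor_config`.
#' @export
read_hfactor_config <- function(path) {
  txt <- readLines(path, warn = FALSE)
  first <- trimws(txt[nzchar(trimws(txt))][1] %||% "")
  if (startsWith(first, "{")) {
    vals <- jsonlite::fromJSON(paste(txt, collapse = "\n"))
  } else {
    txt <- sub("#.*$", "", txt)
    txt <- trimws(txt)
    txt <- txt[nzchar(txt)]
    kv <- strsplit(txt, "\\s*=\\s*")
    if (any(lengths(kv) != 2L))
      stop(data_error(sprintf("malformed config line in '%s'", path)))
    vals <- stats::setNames(lapply(kv, function(p) {
      v <- p[2]
      if (v %in% c("true", "TRUE", "True")) TRUE
      else if (v %in% c("false", "FALSE", "False")) FALSE
      else as.numeric(v)
    }), vapply(kv, `[`, "", 1L))
  }
  unknown <- setdiff(names(vals), names(formals(hfactor_config)))
  if (length(unknown))
    stop(data_error(paste0("unknown config key(s): ",
                           paste(unknown, collapse = ", "))))
  do.call(hfactor_config, vals)
}

clamp01 <- function(x, cfg) if (cfg$clamp) max(0, min(10, x)) else x

#' Secondary-structure agreement score (score 1)
#'
#' Walks the target/template alignment column by column and compares the
#' predicted state of the target residue with the observed state of the
#' aligned template residue. The per-column penalty is 0 on agreement,
#' c(i) + 1 on disagreement (c(i) the integer prediction confidence), and
#' 1 for a column with a gap on either side. The score is
#' `a1 * mean(penalty) + b1`, clamped to [0,10].
#'
#' @param pred an [ss_prediction] covering every ungapped target residue.
#' @param obs an [ss_assignment] covering every ungapped template residue.
#' @param aln a [pair_alignment].
#' @param cfg an [hfactor_config].
#' @return score in [0,10]; 0 is perfect agreement.
#' @export
score1 <- function(pred, obs, aln, cfg = hfactor_config()) {
  stopifnot(inherits(pred, "ss_prediction"), inherits(obs, "ss_assignment"),
            inherits(aln, "pair_alignment"))
  tc <- strsplit(aln$target, "")[[1]]
  mc <- strsplit(aln$template, "")[[1]]
  n_t <- sum(tc != "-")
  n_m <- sum(mc != "-")
  if (length(pred$states) != n_t)
    stop(data_error(sprintf(
      "prediction covers %d residues, target has %d ungapped positions",
      length(pred$states), n_t)))
  if (length(obs$states) != n_m)
    stop(data_error(sprintf(
      "assignment covers %d residues, template has %d ungapped positions",
      length(obs$states), n_m)))
  ti <- 0L; mi <- 0L
  f <- numeric(aln$n)
  for (i in seq_len(aln$n)) {
    tgap <- tc[i] == "-"
    mgap <- mc[i] == "-"
    if (!tgap) ti <- ti + 1L
    if (!mgap) mi <- mi + 1L
    f[i] <- if (tgap || mgap) 1
    else if (pred$states[ti] == obs$states[mi]) 0
    else pred$conf[ti] + 1
  }
  clamp01(cfg$a1 * mean(f) + cfg$b1, cfg)
}

#' Sequence-identity score (score 2)
#'
#' `10 * (1 - identities / N)` over the N columns of the alignment. A
#' column counts as identical when both residues are the same letter
#' (case-insensitive) and neither is a gap or the unknown residue "X";
#' gap columns count as non-identity and remain in N.
#'
#' @param aln a [pair_alignment].
#' @return score in [0,10]; 0 means rows are identical.
#' @export
score2 <- function(aln) {
  stopifnot(inherits(aln, "pair_alignment"))
  tc <- strsplit(toupper(aln$target), "")[[1]]
  mc <- strsplit(toupper(aln$template), "")[[1]]
  ident <- tc == mc & tc != "-" & tc != "X"
  10 * (1 - sum(ident) / aln$n)
}

#' Ensemble-heterogeneity score (score 3)
#'
#' Affine map of the average cRMS between each model and the ensemble's
#' average model: `a3 * spread + b3`, clamped to [0,10]. With the default
#' offsets a spread of 0.1 Angstrom scores 1 and 7 Angstrom scores 10.
#' Returns `NA` (score unavailable) for an ensemble of fewer than two
#' models.
#'
#' @param ensemble a [model_ensemble].
#' @param cfg an [hfactor_config].
#' @param spread optionally, a precomputed [ensemble_spread()] value.
#' @return score in [0,10], or `NA_real_` when n < 2.
#' @export
score3 <- function(ensemble, cfg = hfactor_config(), spread = NULL) {
  if (is.null(spread)) {
    stopifnot(inherits(ensemble, "model_ensemble"))
    if (ensemble$n < 2L) return(NA_real_)
    spread <- ensemble_spread(ensemble)
  }
  clamp01(cfg$a3 * spread + cfg$b3, cfg)
}

#' Domain-consistency score (score 4)
#'
#' For every domain hit on the target, the corresponding fragment of the
#' average model is compared against each reference structure of that
#' domain by alignment-mediated cRMS ([domain_crms()]). The score is
#' `a4 * mean(cRMS over all fragment/reference pairs) + b4`, clamped to
#' [0,10]. Pairs with fewer than 3 aligned positions are skipped with a
#' warning; if no fragment has any usable reference the score is
#' unavailable (`NA`).
#'
#' @param ma an [average_model] (or [ca_structure]) of the target.
#' @param hits list of domain hits from [parse_hmmsearch_domtbl()]
#'   (already E-value-filtered and capped).
#' @param refs a domain reference set from [read_domain_refs()] or
#'   [domain_reference_set()].
#' @param cfg an [hfactor_config].
#' @return score in [0,10], or `NA_real_` when no pair can be scored.
#' @export
score4 <- function(ma, hits, refs, cfg = hfactor_config()) {
  if (!length(hits) || !length(refs)) return(NA_real_)
  struct <- if (inherits(ma, "average_model")) ma$structure else ma
  vals <- numeric(0)
  for (hit in hits) {
    frag <- tryCatch(extract_fragment(struct, hit),
                     error = function(e) NULL)
    if (is.null(frag)) {
      warning(sprintf("domain %s: fragment %d-%d cannot be extracted; skipped",
                      hit$domain_id, hit$start, hit$end), call. = FALSE)
      next
    }
    for (ref in refs[[hit$domain_id]]) {
      v <- domain_crms(frag, ref$structure,
                       seq_a = ca_sequence(frag), seq_b = ref$sequence)
      if (is.na(v)) {
        warning(sprintf(
          "domain %s: fewer than 3 aligned positions with a reference; pair skipped",
          hit$domain_id), call. = FALSE)
        next
      }
      vals <- c(vals, v)
    }
  }
  if (!length(vals)) return(NA_real_)
  clamp01(cfg$a4 * mean(vals) + cfg$b4, cfg)
}

#' Aggregate component scores into the H-factor percentage
#'
#' The aggregate is `100 * sum(available scores) / (10 * number of
#' available scores)`: with all four scores this is the sum divided by 40,
#' and in structure-only mode (scores 3 and 4, as used for NMR-style
#' ensembles) the sum divided by 20, each expressed as a percentage.
#' `mode = "structure_only"` restricts the aggregate to scores 3 and 4
#' even when sequence-based scores are present.
#'
#' @param scores named list or vector with elements s1, s2, s3, s4
#'   (`NA` = unavailable).
#' @param mode "auto" (use whatever is available), "full", or
#'   "structure_only".
#' @return list with `h_percent` (unrounded), `h_percent_rounded`
#'   (nearest integer, half away from zero), `used` (logical vector of
#'   scores entering the aggregate), and `mode`.
#' @examples
#' aggregate_scores(list(s1 = 1.1, s2 = 8.6, s3 = 2.9, s4 = 3.8))  # 41%
#' aggregate_scores(list(s1 = NA, s2 = NA, s3 = 2.13, s4 = 3.43),
#'                  mode = "structure_only")                        # 28%
#' @export
aggregate_scores <- function(scores, mode = c("auto", "full",
                                              "structure_only")) {
  mode <- match.arg(mode)
  s <- vapply(c("s1", "s2", "s3", "s4"), function(k)
    as.numeric(scores[[k]] %||% NA_real_), 0)
  avail <- !is.na(s)
  use <- avail
  if (mode == "structure_only") use <- avail & c(FALSE, FALSE, TRUE, TRUE)
  if (mode == "full" && !all(avail))
    stop(data_error("full-mode aggregation requires all four scores"))
  if (!any(use))
    stop(data_error("no available component scores to aggregate"))
  h <- 100 * sum(s[use]) / (10 * sum(use))
  list(h_percent = h,
       h_percent_rounded = as.integer(round_half_up(h)),
       used = use,
       mode = if (mode == "auto" && !all(use == c(TRUE, TRUE, TRUE, TRUE)))
         "partial" else if (mode == "auto") "full" else mode)
}

# internal constructor for the fitted-object class
new_hfactor <- function(scores, mode, config, label = "target",
                        spread = NULL, avg = NULL, per_model_crms = NULL,
                        agg = NULL, provenance = NULL) {
  agg <- agg %||% aggregate_scores(scores,
                                   mode = if (mode == "structure_only")
                                     "structure_only" else "auto")
  structure(list(label = label,
                 scores = lapply(scores[c("s1", "s2", "s3", "s4")],
                                 function(v) as.numeric(v %||% NA_real_)),
                 mode = mode,
                 h_percent = agg$h_percent,
                 h_percent_rounded = agg$h_percent_rounded,
                 used = agg$used,
                 spread = spread,
                 average_model = avg,
                 per_model_crms = per_model_crms,
                 config = config,
                 provenance = provenance),
            class = "hfactor")
}

#' Compute the H-factor of a homology-model ensemble
#'
#' The main entry point: runs every component score the supplied inputs
#' allow and aggregates them into the H-factor percentage (0% best, 100%
#' worst). The ensemble is mandatory -- the metric measures the
#' heterogeneity of a set of models and cannot be computed on a single
#' model. The other inputs are optional; missing ones make the
#' corresponding scores unavailable and the aggregate degrades to the
#' mean of what remains (e.g. the structure-only mode over scores 3 and 4
#' used for NMR-style ensembles).
#'
#' @param ensemble a [model_ensemble] with at least 2 models (see
#'   [read_ca_models()]).
#' @param alignment optional [pair_alignment] (target vs template).
#' @param ss_pred optional [ss_prediction] for the target.
#' @param ss_assign optional [ss_assignment] for the template; if omitted
#'   but `template` is given, computed internally with
#'   [assign_secondary_structure()].
#' @param hits optional list of domain hits ([parse_hmmsearch_domtbl()]).
#' @param refs optional domain reference set ([read_domain_refs()]).
#' @param template optional template [ca_structure] used only for the
#'   internal secondary-structure fallback.
#' @param mode "auto" selects full or structure-only from the inputs;
#'   "structure_only" forces aggregation over scores 3 and 4 only.
#' @param config an [hfactor_config].
#' @param label target name used in reports.
#' @return an object of class `hfactor` with the four component scores
#'   (`NA` where unavailable), the aggregate percentage, the ensemble
#'   spread, the average model and per-model cRMS values. Methods:
#'   `print`, `summary`, `coef`, `plot`.
#' @examples
#' fx <- make_ensemble(fixture_spec(seed = 1, n_models = 5,
#'                                  n_residues = 30, target_spread = 0.5))
#' h <- hfactor(fx$ensemble)
#' coef(h)
#' @export
hfactor <- function(ensemble, alignment = NULL, ss_pred = NULL,
                    ss_assign = NULL, hits = NULL, refs = NULL,
                    template = NULL,
                    mode = c("auto", "structure_only"),
                    config = hfactor_config(), label = "target") {
  mode <- match.arg(mode)
  stopifnot(inherits(ensemble, "model_ensemble"))
  if (ensemble$n < 2L)
    stop(data_error(paste0(
      "the H-factor cannot be computed on a single model: it measures the ",
      "heterogeneity of an ensemble; supply at least 2 models")))
  if (is.null(ss_assign) && !is.null(template))
    ss_assign <- assign_secondary_structure(template)
  s1 <- if (!is.null(ss_pred) && !is.null(ss_assign) && !is.null(alignment))
    score1(ss_pred, ss_assign, alignment, config) else NA_real_
  s2 <- if (!is.null(alignment)) score2(alignment) else NA_real_
  avg <- average_model(ensemble)
  per <- vapply(ensemble$models, crms, 0, b = avg$structure)
  spread <- mean(per)
  s3 <- score3(ensemble, config, spread = spread)
  s4 <- if (!is.null(hits) && !is.null(refs))
    score4(avg, hits, refs, config) else NA_real_
  scores <- list(s1 = s1, s2 = s2, s3 = s3, s4 = s4)
  eff_mode <- if (mode == "structure_only") "structure_only"
  else if (is.na(s1) && is.na(s2)) "structure_only" else "auto"
  agg <- aggregate_scores(scores, mode = if (eff_mode == "structure_only")
    "structure_only" else "auto")
  new_hfactor(scores, mode = agg$mode, config = config, label = label,
              spread = spread, avg = avg, per_model_crms = per, agg = agg)
}

#' @export
print.hfactor <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "n/a" else sprintf("%.2f", v)
  cat(sprintf("H-factor for '%s' (%s mode)\n", x$label, x$mode))
  cat(sprintf("  score (1) secondary structure : %s\n", fmt(x$scores$s1)))
  cat(sprintf("  score (2) sequence identity   : %s\n", fmt(x$scores$s2)))
  cat(sprintf("  score (3) heterogeneity       : %s\n", fmt(x$scores$s3)))
  cat(sprintf("  score (4) domain consistency  : %s\n", fmt(x$scores$s4)))
  cat(sprintf("  H-factor = %d%%  (0%% best, 100%% worst)\n",
              x$h_percent_rounded))
  invisible(x)
}

#' @export
summary.hfactor <- function(object, ...) {
  print(object)
  if (!is.null(object$spread))
    cat(sprintf("  ensemble spread (mean cRMS to average model): %.3f A\n",
                object$spread))
  if (!is.null(object$per_model_crms)) {
    r <- range(object$per_model_crms)
    cat(sprintf("  per-model cRMS to average model: %.3f - %.3f A over %d models\n",
                r[1], r[2], length(object$per_model_crms)))
  }
  if (!is.null(object$average_model))
    cat(sprintf("  average model converged in %d iteration(s)\n",
                object$average_model$iterations))
  invisible(object)
}

#' @export
coef.hfactor <- function(object, ...) {
  c(s1 = object$scores$s1, s2 = object$scores$s2,
    s3 = object$scores$s3, s4 = object$scores$s4,
    h_percent = object$h_percent)
}

#' @export
plot.hfactor <- function(x, ...) {
  s <- unlist(x$scores)
  op <- graphics::par(mfrow = if (!is.null(x$per_model_crms)) c(1, 2)
                      else c(1, 1))
  on.exit(graphics::par(op))
  graphics::barplot(ifelse(is.na(s), 0, s),
                    names.arg = c("(1) SS", "(2) ID", "(3) het", "(4) dom"),
                    ylim = c(0, 10), ylab = "component score (0 best)",
                    main = sprintf("%s: H = %d%%", x$label,
                                   x$h_percent_rounded), ...)
  if (!is.null(x$per_model_crms)) {
    graphics::plot(x$per_model_crms, type = "h", xlab = "model",
                   ylab = "cRMS to average model (A)",
                   main = "ensemble heterogeneity")
    graphics::abline(h = x$spread, lty = 2)
  }
  invisible(x)
}
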