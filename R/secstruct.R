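# 3-state secondary-structure alphabet and a Calpha-only fallback assigner
# for templates lacking a stride/DSSP file.

#' Default many-state to 3-state reduction table
#'
#' Maps the 7/8-state codes emitted by stride and DSSP onto the 3-state
#' alphabet used by the secondary-structure agreement score: helix classes
#' (H, G, I) to H, extended classes (E, B, b) to S, everything else
#' (turns, polyproline, coil, blanks) to C. The letter S denotes strand in
#' the 3-state alphabet and is a fixed point, which makes the reduction
#' idempotent; DSSP's bend code (also "S") is handled by the DSSP reader,
#' which maps it to blank before reduction.
#'
#' @return named character vector usable as the `table` argument of
#'   [reduce_to_three_state()].
#' @export
default_reduction_table <- function() {
  c(H = "H", G = "H", I = "H",
    E = "S", B = "S", b = "S", S = "S",
    T = "C", P = "C", C = "C", "-" = "C", " " = "C", "~" = "C")
}

#' Reduce a secondary-structure code to 3 states
#'
#' @param code one-letter secondary-structure code (stride/DSSP alphabet,
#'   or already 3-state). An empty or blank code maps to C.
#' @param table reduction table; see [default_reduction_table()].
#' @return one of "H", "S", "C".
#' @examples
#' reduce_to_three_state("G")  # 3-10 helix -> H
#' reduce_to_three_state("B")  # isolated bridge -> S
#' @export
reduce_to_three_state <- function(code, table = default_reduction_table()) {
  if (!nzchar(code)) code <- " "
  out <- table[code]
  if (is.na(out))
    stop(data_error(sprintf(
      "secondary-structure code '%s' is not in the reduction table", code)))
  unname(out)
}

# geometry helpers on the Calpha trace
vec_angle <- function(a, b) {
  cosv <- sum(a * b) / sqrt(sum(a * a) * sum(b * b))
  acos(max(-1, min(1, cosv))) * 180 / pi
}

#' Assign secondary structure from a Calpha trace
#'
#' Calpha-only geometric assigner in the spirit of P-SEA, used as a
#' fallback when no stride/DSSP assignment is supplied for the template.
#' Short-range distances d2 = |i,i+2|, d3 = |i,i+3|, d4 = |i,i+4| are
#' tested against helix and strand windows derived from ideal geometry
#' (alpha-helix: d3 about 5.1 A, d4 about 6.2 A; extended strand:
#' d2 >= 5.5 A, d3 >= 8.5 A). A window satisfying the helix criteria
#' labels residues i..i+3 H; a strand window labels i..i+2 S; helix takes
#' precedence. Chains shorter than 5 residues are labelled all C.
#'
#' @param model a [ca_structure].
#' @return an [ss_assignment], one state per residue.
#' @export
assign_secondary_structure <- function(model) {
  stopifnot(inherits(model, "ca_structure"))
  n <- nresidues(model)
  states <- rep("C", n)
  if (n >= 5L) {
    x <- model$xyz
    d <- function(k) {
      i <- seq_len(n - k)
      sqrt(rowSums((x[i + k, , drop = FALSE] - x[i, , drop = FALSE])^2))
    }
    d2 <- d(2L); d3 <- d(3L); d4 <- d(4L)
    helix_win <- which(d3[seq_along(d4)] >= 4.5 & d3[seq_along(d4)] <= 5.7 &
                         d4 >= 5.5 & d4 <= 6.8)
    strand_win <- which(d2[seq_along(d3)] >= 5.5 & d3 >= 8.5)
    for (i in strand_win) states[i:(i + 2L)] <- "S"
    for (i in helix_win) states[i:(i + 3L)] <- "H"
  }
  ss_assignment(states)
}
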