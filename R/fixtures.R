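# Worked-example models, reconstructed programmatically so that every
# test runs without external files. Rate constants and initial amounts
# are plausible placeholders (the originals' full kinetic
# parameterizations are not part of these toys); structure and counts
# are what matters.

fixture_build <- function(lines) {
  res <- build_model(parse_model(lines), policy = "off")
  errs <- Filter(function(i) identical(i$severity, "error"), res$issues)
  if (length(errs)) {
    stop("fixture failed to build: ",
         paste(vapply(errs, `[[`, "", "message"), collapse = "; "))
  }
  res$model
}

#' Phosphorylation/dephosphorylation chain (Cdh1 by ClbM)
#'
#' A protein `Cdh1` with one phosphorylation-counter site `p{0:maxP}`,
#' phosphorylated by the kinase `ClbM` through a single succ reaction
#' over `p{0:maxP-1}` and dephosphorylated through a single pred
#' reaction over `p{1:maxP}` (first-order mass action; the toy does not
#' name a phosphatase). The aggregate `Cdh1T` tracks total
#' phosphorylated Cdh1 via `SUM(Cdh1;p{1:maxP})`. With the default
#' `maxP = 10` the two collective reactions expand to the 20
#' single-state reactions of the classical explicit encoding.
#'
#' All ranges are written against the global `maxP`, so rescaling the
#' chain is a single-value edit (see [set_global_value()]).
#'
#' @param maxP number of phosphorylation states above zero (>= 1).
#' @return an `msl_model`.
#' @export
cdh1_toy <- function(maxP = 10) {
  stopifnot(maxP >= 1)
  fixture_build(c(
    "[globals]",
    sprintf("maxP = %d", maxP),
    "kp = 1",
    "kd = 0.5",
    "Cdh1T := SUM(Cdh1;p{1:maxP})",
    "[species]",
    "Cdh1(p{0:maxP}) = 1",
    "ClbM = 1",
    "[reactions]",
    "phos : Cdh1(p{0:maxP-1}) + ClbM -> Cdh1(succ(p)) + ClbM | MA : kp",
    "dephos : Cdh1(p{1:maxP}) -> Cdh1(pred(p)) | MA : kd"))
}

#' Distributive multisite phosphorylation (ordered vs disordered)
#'
#' Substrate `XP` with site `i{0:N}` counting phosphorylated residues,
#' phosphorylated by kinase `Kin` in one distributive succ reaction over
#' `i{0:N-1}`. The `ordered` mechanism uses plain mass action with a
#' single rate `k`; the `disordered` mechanism uses the user-defined
#' rate law `dis(GLQ N, SITE i, GLQ k, SUB X, SUB K) = (N-i)*k*X*K`, so
#' the rate of each step scales with the number of still-unphosphorylated
#' sites. Switching mechanism changes only the rate law: both expand to
#' the same N-reaction graph.
#'
#' @param N total number of phosphorylation sites (>= 1).
#' @param mechanism `"ordered"` or `"disordered"`.
#' @return an `msl_model`.
#' @export
xp_phosphorylation <- function(N = 5, mechanism = c("ordered", "disordered")) {
  stopifnot(N >= 1)
  mechanism <- match.arg(mechanism)
  rate <- if (mechanism == "ordered") "MA : k" else "UD : dis(N, XP.i, k, XP, Kin)"
  fixture_build(c(
    "[globals]",
    sprintf("N = %d", N),
    "k = 1",
    "[species]",
    "XP(i{0:N}) = 1",
    "Kin = 1",
    "[functions]",
    "dis(GLQ N, SITE i, GLQ k, SUB X, SUB K) = (N-i)*k*X*K",
    "[reactions]",
    sprintf("phos : XP(i{0:N-1}) + Kin -> XP(succ(i)) + Kin | %s", rate)))
}

#' Ribosome translocation toy with a moving-window aggregate modifier
#'
#' A ribosome-like species `R` sits at codon `c{1:len}` of an mRNA
#' chain; translocation over the queue-sensitive window `c{1:d}` moves
#' the state forward with transfer of state (`P1(c=succ(R.c))`) and
#' releases `P2`. The aggregate modifier `M(c)` -- a multistate species
#' with no state values of its own -- is assigned per instance the total
#' occupancy of the next `window` codons,
#' `SUM(R;c{M.c+1:M.c+window})`, truncated at the chain end (a ribosome
#' near the 3' end sees a shorter window, not an error). Scaling the
#' chain from 20 to, say, 300 codons is a single change of `len`.
#'
#' @param length chain length in codons.
#' @param d last codon of the queue-sensitive region (1 <= d < length).
#' @param window width of the occupancy window in codons.
#' @return an `msl_model`.
#' @export
translation_toy <- function(length = 20, d = 3, window = 14) {
  stopifnot(d >= 1, d < length)
  fixture_build(c(
    "[globals]",
    sprintf("len = %d", length),
    sprintf("d = %d", d),
    sprintf("w = %d", window),
    "ktr = 1",
    "[species]",
    "R(c{1:len}) = 1",
    "P1(c{1:len}) = 0",
    "P2 = 0",
    "M(c) := SUM(R;c{M.c+1:M.c+w})",
    "[reactions]",
    "transloc : R(c{1:d}) -> P1(c=succ(R.c)) + P2; M(c=R.c) | MA : ktr"))
}

#' Species with symbolic and nonconsecutive integer states
#'
#' One species carrying a site with symbolic states
#' `s1{free,bound,hidden}` and a site with nonconsecutive integer states
#' `s2{2,4,6,8,0}` (double-phosphorylation steps in one event), plus a
#' reaction stepping both with succ: the successor of `free` is `bound`
#' and the successor of `2` is `4` -- order is declaration order, the
#' labels carry no numeric meaning.
#'
#' @return an `msl_model`.
#' @export
nonconsecutive_demo <- function() {
  fixture_build(c(
    "[globals]",
    "k = 1",
    "[species]",
    "S(s1{free,bound,hidden}, s2{2,4,6,8,0}) = 1",
    "[reactions]",
    "step : S(s1{free}, s2{2}) -> S(succ(s1), succ(s2)) | MA : k"))
}

#' Change the value of a fixed global quantity
#'
#' The one-line edit that re-parameterizes every range written against
#' the global (chain lengths, window widths); re-expansion then yields
#' the new network with no other changes.
#'
#' @param model an `msl_model`.
#' @param name a fixed global quantity.
#' @param value new numeric value.
#' @return the updated model.
#' @export
set_global_value <- function(model, name, value) {
  g <- model$globals[[name]]
  if (is.null(g)) stop("no global quantity named '", name, "'")
  if (!identical(g$role, "fixed")) {
    stop("'", name, "' is an assigned quantity; set its expression instead")
  }
  model$globals[[name]]$expr <- e_num(value)
  model
}
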