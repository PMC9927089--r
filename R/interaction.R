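# Zinc-arginine interaction index.
#
# A modified fractional-inhibitory-concentration (FIC) index in which the
# minimal inhibitory concentrations are replaced by Young's moduli: the
# stiffness of the combination-treated biofilm is referenced to each
# single-agent stiffness, and the two ratios are summed. Low values mean the
# combination softens the biofilm far beyond either agent alone (synergism);
# high values mean the agents work against each other (antagonism).

#' Classify an interaction index value
#'
#' Synergism when `IAI <= 0.5`, additive when `0.5 < IAI < 4`, antagonism when
#' `IAI >= 4`. The printed rule assigns 4 to both the additive ("> 0.5 to 4")
#' and antagonism (">= 4") ranges; exactly 4 is resolved to antagonism here
#' because its bound is the explicit inequality.
#'
#' @param iai positive interaction index (vectorised).
#' @return character vector in `{"synergism", "additive", "antagonism"}`.
#' @export
classify_interaction <- function(iai) {
  if (any(!is.finite(iai)) || any(iai <= 0))
    stop("interaction index must be > 0", call. = FALSE)
  ifelse(iai <= 0.5, "synergism", ifelse(iai >= 4, "antagonism", "additive"))
}

#' Interaction index from group Young's moduli
#'
#' `IAI_Arg = E_DZA / E_Arg`, `IAI_Zn = E_DZA / E_Zn`, `IAI = IAI_Arg +
#' IAI_Zn`, where `E_DZA` is the modulus of biofilms treated with the
#' zinc-plus-arginine combination and `E_Arg`, `E_Zn` the single-agent
#' moduli. The index is scale invariant: any common unit cancels.
#'
#' @param e_dza,e_arg,e_zn Young's moduli (any common unit), > 0.
#' @return object of class `interaction_index` with `iai_arg`, `iai_zn`,
#'   `iai` and `classification`.
#' @examples
#' interaction_index(9.29, 15.38, 11.14)  # additive, IAI ~= 1.44
#' @export
interaction_index <- function(e_dza, e_arg, e_zn) {
  for (v in list(e_dza = e_dza, e_arg = e_arg, e_zn = e_zn))
    if (any(!is.finite(v)) || any(v <= 0))
      stop("all moduli must be finite and > 0", call. = FALSE)
  iai_arg <- e_dza / e_arg
  iai_zn <- e_dza / e_zn
  iai <- iai_arg + iai_zn
  structure(list(iai_arg = iai_arg, iai_zn = iai_zn, iai = iai,
                 classification = classify_interaction(iai),
                 boundary_rule = "IAI of exactly 4 classified as antagonism"),
            class = "interaction_index")
}

#' @export
print.interaction_index <- function(x, ...) {
  if (length(x$iai) == 1L) {
    cat(sprintf("Interaction index: %.4g (arginine term %.4g + zinc term %.4g) -> %s\n",
                x$iai, x$iai_arg, x$iai_zn, x$classification))
  } else {
    cat(sprintf("Interaction indices (n = %d): mean %.4g, range [%.4g, %.4g]\n",
                length(x$iai), mean(x$iai), min(x$iai), max(x$iai)))
  }
  invisible(x)
}

#' Per-replicate table of Young's moduli
#'
#' @param group treatment label per record; the interaction analysis expects
#'   `"untreated"`, `"arginine"`, `"zinc"` and `"dza"` labels.
#' @param replicate replicate identifier per record.
#' @param E Young's modulus per record, > 0 (any single consistent unit).
#' @return a `modulus_table` data frame.
#' @export
modulus_table <- function(group, replicate, E) {
  if (any(!is.finite(E)) || any(E <= 0))
    stop("all moduli must be finite and > 0", call. = FALSE)
  structure(data.frame(group = as.character(group),
                       replicate = replicate, E = E),
            class = c("modulus_table", "data.frame"))
}

#' Replicate-level interaction-index summary
#'
#' Computes the interaction index per replicate rather than from group means.
#' `"matched"` pairing uses the same replicate index across the dza, arginine
#' and zinc groups (parallel discs per biological replicate); the
#' `"all-combinations"` sensitivity analysis forms every cross-group triple.
#'
#' @param table a [modulus_table()] with `dza`, `arginine` and `zinc` groups,
#'   each with at least 2 replicates.
#' @param pairing `"matched"` or `"all-combinations"`.
#' @return list with `mean`, `sd`, `values` (per-replicate indices),
#'   `classification` (of the mean) and `pairing`.
#' @export
replicate_interaction_summary <- function(table,
                                          pairing = c("matched",
                                                      "all-combinations")) {
  pairing <- match.arg(pairing)
  pull <- function(g) {
    e <- table$E[table$group == g]
    if (length(e) < 2L)
      stop("group '", g, "' needs at least 2 replicates (found ",
           length(e), ")", call. = FALSE)
    e
  }
  dza <- pull("dza"); arg <- pull("arginine"); zn <- pull("zinc")
  if (pairing == "matched") {
    if (length(unique(c(length(dza), length(arg), length(zn)))) != 1L)
      stop("matched pairing needs equal replicate counts per group ",
           "(dza ", length(dza), ", arginine ", length(arg), ", zinc ",
           length(zn), "); use pairing = \"all-combinations\"", call. = FALSE)
    values <- dza / arg + dza / zn
  } else {
    triples <- expand.grid(dza = dza, arg = arg, zn = zn)
    values <- triples$dza / triples$arg + triples$dza / triples$zn
  }
  list(mean = mean(values), sd = stats::sd(values), values = values,
       classification = classify_interaction(mean(values)), pairing = pairing)
}

#' Difference and ratio of single-agent moduli
#'
#' Companion comparison to the interaction index: if arginine and zinc act on
#' the same biofilm component, the combination modulus should resemble the
#' single-agent moduli divided rather than subtracted. Vectorised; when given
#' per-replicate vectors the mean and SD of each quantity are included.
#'
#' @param e_arg,e_zn Young's moduli (> 0), scalars or equal-length vectors.
#' @return list with `difference` and `ratio` (per element), plus
#'   `difference_mean`, `difference_sd`, `ratio_mean`, `ratio_sd` when input
#'   length exceeds 1.
#' @export
modulus_difference_and_ratio <- function(e_arg, e_zn) {
  if (any(!is.finite(e_arg)) || any(!is.finite(e_zn)) ||
      any(e_arg <= 0) || any(e_zn <= 0))
    stop("all moduli must be finite and > 0", call. = FALSE)
  if (length(e_arg) != length(e_zn))
    stop("'e_arg' and 'e_zn' must have equal length", call. = FALSE)
  out <- list(difference = e_arg - e_zn, ratio = e_arg / e_zn)
  if (length(e_arg) > 1L) {
    out$difference_mean <- mean(out$difference)
    out$difference_sd <- stats::sd(out$difference)
    out$ratio_mean <- mean(out$ratio)
    out$ratio_sd <- stats::sd(out$ratio)
  }
  out
}
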