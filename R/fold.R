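#' Simplified nearest-pair energy model
#'
#' The built-in folding engine scores a secondary structure as the sum of
#' independent base-pair energies (no stacking or loop terms). This keeps
#' every downstream quantity verifiable by exhaustive enumeration while the
#' external-folder adapter ([external_fold_adapter()]) recovers full
#' thermodynamic fidelity when a Turner-parameter folder is installed.
#'
#' @param pair_energies named numeric vector of energies (kcal/mol, negative)
#'   for the canonical pair types `GC`, `AU`, `GU`.
#' @param min_hairpin minimum number of unpaired nucleotides enclosed by any
#'   base pair.
#' @param kT thermal energy in kcal/mol; the default 0.6 kcal corresponds to
#'   37 degrees C and is the constant used in the active-conformation
#'   probability.
#' @param allow_lone_pairs logical; the builtin engine supports only `TRUE`
#'   (lone pairs permitted, as in the analyses this package models).
#' @return an object of class `energy_model`.
#' @export
energy_model <- function(pair_energies = c(GC = -3.0, AU = -2.0, GU = -1.0),
                         min_hairpin = 3L, kT = 0.6, allow_lone_pairs = TRUE) {
  stopifnot(all(c("GC", "AU", "GU") %in% names(pair_energies)))
  if (any(pair_energies >= 0)) stop("all pair energies must be negative")
  if (min_hairpin < 3L) stop("min_hairpin must be >= 3")
  if (kT <= 0) stop("kT must be positive")
  if (!allow_lone_pairs)
    stop("the builtin engine does not support forbidding lone pairs; ",
         "use the external backend")
  structure(list(pair_energies = pair_energies,
                 min_hairpin = as.integer(min_hairpin),
                 kT = kT, allow_lone_pairs = allow_lone_pairs),
            class = "energy_model")
}

#' @export
print.energy_model <- function(x, ...) {
  cat("Simplified pair energy model\n")
  cat("  pair energies (kcal/mol):",
      paste(names(x$pair_energies), x$pair_energies, sep = "=", collapse = ", "),
      "\n")
  cat("  min hairpin:", x$min_hairpin, " kT:", x$kT, "kcal/mol\n")
  invisible(x)
}

NT_CODE <- c(A = 0L, C = 1L, G = 2L, U = 3L)
CONS_CODE <- c("." = 0L, "x" = 1L, "|" = 2L, "<" = 3L, ">" = 4L)

encode_seq <- function(sequence) {
  sequence <- toupper(sequence)
  sequence <- gsub("T", "U", sequence, fixed = TRUE)
  v <- strsplit(sequence, "")[[1]]
  bad <- setdiff(unique(v), names(NT_CODE))
  if (length(bad)) stop("invalid nucleotide(s): ", paste(bad, collapse = ", "))
  unname(NT_CODE[v])
}

encode_constraint <- function(constraint, n) {
  if (is.null(constraint)) return(rep(0L, n))
  v <- strsplit(constraint, "")[[1]]
  if (length(v) != n) stop("constraint length ", length(v),
                           " does not match sequence length ", n)
  bad <- setdiff(unique(v), names(CONS_CODE))
  if (length(bad)) stop("invalid constraint symbol(s): ",
                        paste(bad, collapse = ", "))
  unname(CONS_CODE[v])
}

pair_energy_matrix <- function(model) {
  m <- matrix(1, 4, 4, dimnames = list(names(NT_CODE), names(NT_CODE)))
  e <- model$pair_energies
  m["G", "C"] <- m["C", "G"] <- e[["GC"]]
  m["A", "U"] <- m["U", "A"] <- e[["AU"]]
  m["G", "U"] <- m["U", "G"] <- e[["GU"]]
  m
}

#' Convert a pair table to dot-bracket notation
#'
#' @param partner integer vector, `partner[i]` the 1-based pairing partner of
#'   position `i` (0 when unpaired).
#' @return dot-bracket string.
#' @export
pairs_to_dotbracket <- function(partner) {
  ch <- rep(".", length(partner))
  ch[partner > seq_along(partner)] <- "("
  ch[partner != 0 & partner < seq_along(partner)] <- ")"
  paste(ch, collapse = "")
}

#' Minimum free energy structure under the builtin model
#'
#' Computes the structure of minimal energy by dynamic programming, honouring
#' hard constraints. Ties between equal-energy structures are broken
#' deterministically: the leftmost differing position is preferred paired,
#' and paired to its 5'-most admissible partner.
#'
#' @param sequence RNA string over A/C/G/U (T accepted and mapped to U).
#' @param model an [energy_model()].
#' @param constraint optional constraint string over `. x | < >` where `x`
#'   forces a position unpaired, `|` paired, `<` paired with a downstream
#'   partner and `>` paired with an upstream partner.
#' @return list with `structure` (dot-bracket) and `energy` (kcal/mol).
#' @export
fold_mfe <- function(sequence, model = energy_model(), constraint = NULL) {
  s <- encode_seq(sequence)
  cons <- encode_constraint(constraint, length(s))
  res <- .fold_dp(s, cons, pair_energy_matrix(model), model$min_hairpin,
                  model$kT, FALSE, FALSE)
  if (!res$satisfiable)
    stop("constraint is unsatisfiable for this sequence")
  list(structure = pairs_to_dotbracket(res$partner), energy = res$mfe_energy)
}

#' Partition function and pair probabilities
#'
#' Computes the Boltzmann partition function Z over all structures valid
#' under the model (and constraint, when given), the ensemble free energy
#' G = -kT log Z, and optionally the base-pair probability matrix from the
#' outside (McCaskill) recursion.
#'
#' @inheritParams fold_mfe
#' @param want_bpp logical; compute the pair-probability matrix (O(n^4)).
#' @return list with `log_z`, `z`, `ensemble_energy`, and `bp_prob` (an
#'   upper-triangular matrix) when requested.
#' @export
partition_function <- function(sequence, model = energy_model(),
                               constraint = NULL, want_bpp = TRUE) {
  s <- encode_seq(sequence)
  cons <- encode_constraint(constraint, length(s))
  res <- .fold_dp(s, cons, pair_energy_matrix(model), model$min_hairpin,
                  model$kT, TRUE, want_bpp)
  if (!res$satisfiable)
    stop("constraint is unsatisfiable for this sequence")
  out <- list(log_z = res$log_z, z = exp(res$log_z),
              ensemble_energy = -model$kT * res$log_z)
  if (want_bpp) out$bp_prob <- res$bpp
  out
}

#' Full fold of one sequence: MFE plus ensemble quantities
#'
#' Convenience wrapper producing the complete `fold_result` used by
#' featurization: MFE structure and energy, ensemble free energy, MFE
#' frequency, ensemble diversity, and pair probabilities.
#'
#' @inheritParams fold_mfe
#' @param want_bpp compute pair probabilities (needed for ensemble diversity).
#' @return object of class `fold_result`.
#' @export
fold_sequence <- function(sequence, model = energy_model(), constraint = NULL,
                          want_bpp = TRUE) {
  mfe <- fold_mfe(sequence, model, constraint)
  pf <- partition_function(sequence, model, constraint, want_bpp = want_bpp)
  em <- ensemble_metrics(mfe$energy, pf$log_z, model$kT,
                         if (want_bpp) pf$bp_prob else NULL)
  structure(list(sequence = toupper(gsub("T", "U", sequence, fixed = TRUE)),
                 mfe_structure = mfe$structure, mfe_energy = mfe$energy,
                 ensemble_energy = pf$ensemble_energy,
                 mfe_frequency = em$mfe_frequency,
                 ensemble_diversity = em$ensemble_diversity,
                 bp_prob = if (want_bpp) pf$bp_prob else NULL),
            class = "fold_result")
}

#' @export
print.fold_result <- function(x, ...) {
  cat(x$sequence, "\n", x$mfe_structure, sprintf(" (%.2f)\n", x$mfe_energy),
      sep = "")
  cat(sprintf("  ensemble G = %.3f kcal/mol, MFE frequency = %.4f",
              x$ensemble_energy, x$mfe_frequency))
  if (!is.na(x$ensemble_diversity))
    cat(sprintf(", diversity = %.3f nt", x$ensemble_diversity))
  cat("\n")
  invisible(x)
}

#' Ensemble-level summary statistics
#'
#' MFE frequency is the Boltzmann probability of the MFE structure,
#' `exp(-(E_MFE - G)/kT)`. Ensemble diversity is the expected base-pair
#' distance between two structures drawn independently from the ensemble,
#' `2 * sum_{i<j} p_ij (1 - p_ij)`.
#'
#' @param mfe_energy MFE energy (kcal/mol).
#' @param log_z log of the partition function (same model/constraint).
#' @param kT thermal energy (kcal/mol).
#' @param bp_prob optional pair-probability matrix; diversity is `NA` without
#'   it.
#' @return list with `mfe_frequency` and `ensemble_diversity`.
#' @export
ensemble_metrics <- function(mfe_energy, log_z, kT = 0.6, bp_prob = NULL) {
  freq <- exp(-mfe_energy / kT - log_z)
  div <- NA_real_
  if (!is.null(bp_prob)) {
    p <- bp_prob[upper.tri(bp_prob)]
    div <- 2 * sum(p * (1 - p))
  }
  list(mfe_frequency = freq, ensemble_diversity = div)
}

#' Probability of the catalytically active (WT-like) conformation
#'
#' Boltzmann weight of the constrained WT-like state over the unconstrained
#' partition function, `exp(-E_wt/kT) / Z`, divided by the number of
#' reference core pairs that the variant sequence can no longer form as
#' canonical (Watson-Crick or GU) pairs; the divisor is 1 when that count is
#' zero. `E_wt` is the energy of the minimum-energy structure satisfying the
#' substrate's constraint string. When the constraint is unsatisfiable for a
#' variant the probability is `NA` with `satisfiable = FALSE`, which
#' featurization propagates as an explicitly missing value.
#'
#' @inheritParams fold_mfe
#' @param constraint the substrate-level constraint string (see [fold_mfe()]).
#' @param reference the substrate-level reference dot-bracket marking the
#'   required core pairing of the WT-like state.
#' @return object of class `active_conf_result` with fields `e_wt`, `log_z`,
#'   `noncanonical_core_count`, `probability`, `satisfiable`.
#' @export
active_conformation_probability <- function(sequence, model = energy_model(),
                                            constraint, reference) {
  s <- encode_seq(sequence)
  n <- length(s)
  if (is.null(constraint)) constraint <- strrep(".", n)
  if (is.null(reference)) reference <- strrep(".", n)
  if (nchar(constraint) != n || nchar(reference) != n)
    stop("sequence, constraint and reference lengths differ")
  ref_pt <- parse_dotbracket(reference)

  # count reference core pairs that the variant cannot form canonically
  pe <- pair_energy_matrix(model)
  ntc <- names(NT_CODE)
  idx <- which(ref_pt$partner > seq_len(n))
  noncanon <- 0L
  for (i in idx) {
    j <- ref_pt$partner[i]
    if (pe[ntc[s[i] + 1L], ntc[s[j] + 1L]] >= 0) noncanon <- noncanon + 1L
  }

  pf <- partition_function(sequence, model, constraint = NULL,
                           want_bpp = FALSE)
  cons <- encode_constraint(constraint, n)
  cres <- .fold_dp(s, cons, pe, model$min_hairpin, model$kT, FALSE, FALSE)
  if (!cres$satisfiable) {
    return(structure(list(e_wt = NA_real_, log_z = pf$log_z,
                          noncanonical_core_count = noncanon,
                          probability = NA_real_, satisfiable = FALSE),
                     class = "active_conf_result"))
  }
  e_wt <- cres$mfe_energy
  prob <- exp(-e_wt / model$kT - pf$log_z) / max(1L, noncanon)
  structure(list(e_wt = e_wt, log_z = pf$log_z,
                 noncanonical_core_count = noncanon,
                 probability = prob, satisfiable = TRUE),
            class = "active_conf_result")
}

#' Exhaustive structure enumeration (test oracle)
#'
#' Enumerates every secondary structure valid under the model and constraint
#' for short sequences. Used as the independent oracle that the dynamic
#' programming engine is checked against; intentionally written as plain
#' recursion with none of the DP machinery.
#'
#' @inheritParams fold_mfe
#' @param max_len guard on sequence length (enumeration is exponential).
#' @return data.frame with columns `structure` (dot-bracket) and `energy`.
#' @export
brute_force_fold <- function(sequence, model = energy_model(),
                             constraint = NULL, max_len = 22L) {
  s <- encode_seq(sequence)
  n <- length(s)
  if (n > max_len) stop("sequence longer than max_len = ", max_len)
  cons <- encode_constraint(constraint, n)
  pe <- pair_energy_matrix(model)
  mh <- model$min_hairpin
  can_pair <- function(i, j) {
    (j - i - 1 >= mh) && pe[s[i] + 1L, s[j] + 1L] < 0 &&
      cons[i] %in% c(0L, 2L, 3L) && cons[j] %in% c(0L, 2L, 4L)
  }
  can_unpair <- function(p) cons[p] %in% c(0L, 1L)
  # enumerate pair sets over [i, j]; returns list of (pairs matrix)
  enum <- function(i, j) {
    if (i > j) return(list(matrix(integer(), ncol = 2)))
    out <- list()
    if (can_unpair(i)) out <- enum(i + 1L, j)
    ks <- seq_len(j - i)[-seq_len(min(mh, j - i))] + i
    for (k in ks) {
      if (!can_pair(i, k)) next
      inner <- enum(i + 1L, k - 1L)
      outer <- enum(k + 1L, j)
      for (a in inner) for (b in outer)
        out[[length(out) + 1L]] <- rbind(a, b, c(i, k))
    }
    out
  }
  structs <- enum(1L, n)
  if (!length(structs)) stop("constraint is unsatisfiable for this sequence")
  db <- character(length(structs))
  en <- numeric(length(structs))
  for (q in seq_along(structs)) {
    p <- structs[[q]]
    partner <- integer(n)
    e <- 0
    if (nrow(p)) {
      partner[p[, 1]] <- p[, 2]
      partner[p[, 2]] <- p[, 1]
      e <- sum(pe[cbind(s[p[, 1]] + 1L, s[p[, 2]] + 1L)])
    }
    db[q] <- pairs_to_dotbracket(partner)
    en[q] <- e
  }
  data.frame(structure = db, energy = en, stringsAsFactors = FALSE)
}

#' Fold through a named backend
#'
#' Backend-agnostic adapter so downstream stages never depend on which
#' folder produced a result. `builtin` uses the package's own engine;
#' `vienna` shells out to `RNAfold` when it is installed on the system and
#' raises an explicit capability error when it is not (never a silent
#' fallback).
#'
#' @inheritParams fold_mfe
#' @param backend `"builtin"` or `"vienna"`.
#' @param want_bpp compute pair probabilities.
#' @return a `fold_result` (see [fold_sequence()]).
#' @export
external_fold_adapter <- function(sequence, constraint = NULL,
                                  backend = c("builtin", "vienna"),
                                  model = energy_model(), want_bpp = TRUE) {
  backend <- match.arg(backend)
  if (backend == "builtin")
    return(fold_sequence(sequence, model, constraint, want_bpp = want_bpp))
  rnafold <- Sys.which("RNAfold")
  if (!nzchar(rnafold))
    stop("backend 'vienna' requested but RNAfold is not on PATH")
  out <- system2(rnafold, c("--noPS", "-p", "-d2"), input = sequence,
                 stdout = TRUE)
  line2 <- strsplit(out[2], " ", fixed = TRUE)[[1]]
  db <- line2[1]
  energy <- as.numeric(gsub("[()]", "", paste(line2[-1], collapse = "")))
  structure(list(sequence = sequence, mfe_structure = db, mfe_energy = energy,
                 ensemble_energy = NA_real_, mfe_frequency = NA_real_,
                 ensemble_diversity = NA_real_, bp_prob = NULL),
            class = "fold_result")
}
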