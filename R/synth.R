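#' Specification of a synthetic editing substrate and library
#'
#' The generator emulates the hairpin-with-internal-loops substrates used in
#' saturation-mutagenesis editing studies: a stack of stems separated by
#' small internal loops, the editing site an A inside a 1:1 internal loop
#' (opposite a C when `site_ac`), flanking exterior tails. Editing levels are
#' planted as a logistic function of structural features with replicate
#' Gaussian noise, and reads are drawn binomially at a set coverage.
#'
#' @param seed integer seed controlling every random choice downstream.
#' @param ext lengths of the 5'/3' exterior tails.
#' @param stems stem lengths (bp), outermost first.
#' @param loops list of internal-loop dims `c(n5, n3)` between consecutive
#'   stems (length `length(stems) - 1`).
#' @param hairpin hairpin-loop length (nt).
#' @param site_loop which internal loop holds the editing site (its 5' nt).
#' @param site_ac logical; place a C opposite the edited A.
#' @param n_singles,n_doubles,n_indels library composition.
#' @param weights planted-editing weights for
#'   `c(active_conf, sim_score, num_mutations, site_ac)`.
#' @param wt_editing target WT editing level (0.66 mirrors a highly edited
#'   natural substrate).
#' @param noise_sd replicate noise standard deviation.
#' @param n_reps biological replicates per variant.
#' @param coverage reads per variant for the read simulator.
#' @param error_rate per-base sequencing error rate.
#' @return object of class `synth_spec`.
#' @export
synth_spec <- function(seed = 1L, ext = c(4L, 4L), stems = c(7L, 5L, 5L),
                       loops = list(c(2L, 2L), c(1L, 1L)), hairpin = 5L,
                       site_loop = 2L, site_ac = TRUE,
                       n_singles = 60L, n_doubles = 20L, n_indels = 4L,
                       weights = c(active_conf = 2.5, sim = 2.0,
                                   num_mut = 0.4, site_ac = 0.8),
                       wt_editing = 0.66, noise_sd = 0.02, n_reps = 6L,
                       coverage = 2000L, error_rate = 0) {
  stopifnot(length(loops) == length(stems) - 1L,
            site_loop >= 1L, site_loop <= length(loops),
            noise_sd >= 0, n_singles >= 0, n_doubles >= 0, n_indels >= 0)
  structure(as.list(environment()), class = "synth_spec")
}

# layout bookkeeping: positions of every designed element
synth_layout <- function(spec) {
  ns <- length(spec$stems)
  ch <- character(0); tag <- character(0)
  push <- function(sym, lab, k) {
    ch <<- c(ch, rep(sym, k)); tag <<- c(tag, rep(lab, k))
  }
  push(".", "ext5", spec$ext[1])
  for (q in seq_len(ns)) {
    push("(", paste0("stem", q, "_5"), spec$stems[q])
    if (q < ns) push(".", paste0("loop", q, "_5"), spec$loops[[q]][1])
  }
  push(".", "hairpin", spec$hairpin)
  for (q in rev(seq_len(ns))) {
    if (q < ns) push(".", paste0("loop", q, "_3"), spec$loops[[q]][2])
    push(")", paste0("stem", q, "_3"), spec$stems[q])
  }
  push(".", "ext3", spec$ext[2])
  list(structure = paste(ch, collapse = ""), tags = tag,
       site = which(tag == paste0("loop", spec$site_loop, "_5"))[1],
       opp = rev(which(tag == paste0("loop", spec$site_loop, "_3")))[1])
}

#' Generate a synthetic substrate
#'
#' Samples stem and loop nucleotides (seeded) until the builtin-model MFE
#' structure equals the designed dot-bracket, then derives the substrate's
#' constraint and reference strings from the designed core (the stems
#' flanking the editing-site loop): the reference keeps exactly the core
#' pairs, and the constraint marks each core pair's 3' partner with `>`
#' (must pair upstream).
#'
#' @param spec a [synth_spec()].
#' @param model [energy_model()].
#' @param max_tries attempts before declaring the layout infeasible.
#' @return a [substrate()].
#' @export
gen_substrate <- function(spec, model = energy_model(), max_tries = 100L) {
  set.seed(spec$seed)
  lay <- synth_layout(spec)
  pt <- parse_dotbracket(lay$structure)$partner
  n <- nchar(lay$structure)
  pair_pool <- c("G:C", "C:G", "A:U", "U:A")
  pair_w <- c(.38, .38, .12, .12)
  core_stems <- paste0("stem", c(spec$site_loop, spec$site_loop + 1L), "_5")

  for (try in seq_len(max_tries)) {
    v <- character(n)
    for (i in which(pt > seq_len(n))) {
      pr <- strsplit(sample(pair_pool, 1, prob = pair_w), ":")[[1]]
      v[i] <- pr[1]; v[pt[i]] <- pr[2]
    }
    unp <- which(pt == 0L)
    v[unp] <- sample(c("A", "C"), length(unp), TRUE, prob = c(.6, .4))
    v[lay$site] <- "A"
    if (spec$site_ac) v[lay$opp] <- "C"
    seqn <- paste(v, collapse = "")
    mfe <- fold_mfe(seqn, model)
    if (mfe$structure == lay$structure) {
      core_pos <- which(lay$tags %in% core_stems)
      ref <- rep(".", n); cons <- rep(".", n)
      ref[core_pos] <- "("; ref[pt[core_pos]] <- ")"
      cons[pt[core_pos]] <- ">"
      return(substrate(name = sprintf("synth_seed%d", spec$seed),
                       wt_sequence = seqn, editing_site = lay$site,
                       constraint = paste(cons, collapse = ""),
                       reference = paste(ref, collapse = ""),
                       wt_structure = lay$structure, model = model))
    }
  }
  stop("infeasible layout: no sampled sequence folded into the design in ",
       max_tries, " tries")
}

#' Generate a synthetic variant library (sequences only)
#'
#' Samples `n_singles` single substitutions (excluding the editing site and
#' A>G at its -1/+1 neighbours, indistinguishable from editing),
#' `n_doubles` double transversions, and `n_indels` short (<= 3 nt) loop
#' indels; deduplicated, WT row included.
#'
#' @param sub a [substrate()] from [gen_substrate()].
#' @param spec the same [synth_spec()].
#' @return a `variant_library`.
#' @export
gen_library <- function(sub, spec) {
  set.seed(spec$seed + 1L)
  n <- nchar(sub$wt_sequence)
  v <- strsplit(sub$wt_sequence, "")[[1]]
  es <- sub$editing_site
  nbr <- intersect(c(es - 1L, es + 1L), seq_len(n))
  excl <- data.frame(pos = nbr, ref = "A", alt = "G")
  all_singles <- enumerate_designed_variants(
    sub, list(regions = list(c(1L, n)), exclude = excl))
  cand <- all_singles$mutations[all_singles$mutations != ""]
  singles <- sample(cand, min(spec$n_singles, length(cand)))

  # doubles are designed over a disjoint matching of positions (plus
  # compensatory pair swaps at WT stem pairs) so that co-mutation groups --
  # which must share a train/test split -- stay small instead of
  # transitively merging the whole molecule into one group
  positions <- setdiff(seq_len(n), es)
  tv <- function(ref) if (ref %in% c("A", "G")) c("C", "U") else c("A", "G")
  shuf <- sample(positions)
  shuf <- shuf[seq_len(2L * (length(shuf) %/% 2L))]
  pool <- character(0)
  for (q in seq(1L, length(shuf), by = 2L)) {
    pp <- sort(shuf[q:(q + 1L)])
    for (a1 in tv(v[pp[1]])) for (a2 in tv(v[pp[2]]))
      pool <- c(pool, paste0(pp[1], ":", v[pp[1]], ">", a1, ";",
                             pp[2], ":", v[pp[2]], ">", a2))
  }
  pt_wt <- parse_dotbracket(sub$wt_structure)$partner
  comp_i <- setdiff(which(pt_wt > seq_len(n)), c(es, pt_wt[es]))
  comp_i <- comp_i[!pt_wt[comp_i] %in% c(es)]
  comp <- vapply(comp_i, function(i) {
    j <- pt_wt[i]
    paste0(i, ":", v[i], ">", v[j], ";", j, ":", v[j], ">", v[i])
  }, character(1))
  pool <- unique(c(pool, comp))
  doubles <- sample(pool, min(spec$n_doubles, length(pool)))

  unpaired <- which(parse_dotbracket(sub$wt_structure)$partner == 0L)
  loop_pos <- setdiff(unpaired, c(es, nbr))
  indels <- character(0)
  while (length(indels) < spec$n_indels && length(loop_pos) > 1L) {
    p <- sample(loop_pos, 1L)
    ind <- if (runif(1) < 0.5)
      paste0(p, ":ins:", paste(sample(c("A", "C", "U"),
                                      sample(1:3, 1), TRUE), collapse = ""))
    else paste0(p, ":del:1")
    indels <- unique(c(indels, ind))
  }

  muts <- unique(c(singles, doubles, indels))
  seqs <- vapply(muts, function(m) apply_mutations(sub$wt_sequence, m),
                 character(1))
  new_variant_library(data.frame(
    id = c("WT", sprintf("var%03d", seq_along(muts))),
    mutations = c("", muts), sequence = c(sub$wt_sequence, unname(seqs)),
    stringsAsFactors = FALSE))
}

# per-variant structural drivers of the planted editing function
planted_drivers <- function(library, sub, model = energy_model()) {
  wt_tree <- to_tree(annotate_elements(parse_dotbracket(sub$wt_structure),
                                       sub$wt_sequence))
  t(vapply(seq_len(nrow(library)), function(q) {
    seqn <- library$sequence[q]
    # indel variants change length: the substrate-level constraint cannot
    # apply, so the active conformation is flagged incomputable
    acp <- tryCatch(
      active_conformation_probability(seqn, model, sub$constraint,
                                      sub$reference),
      error = function(e) list(satisfiable = FALSE))
    mfe <- fold_mfe(seqn, model)
    els <- annotate_elements(parse_dotbracket(mfe$structure), seqn)
    sim <- similarity_score(to_tree(els), wt_tree)
    es <- variant_editing_site(sub, library$mutations[q])
    ctx <- locate_site_context(els, es, seqn)
    ac <- as.numeric(ctx$site$kind == "internal" &&
                     all(ctx$site$dims == c(1, 1)) &&
                     substr(seqn, es, es) == "A" &&
                     identical(ctx$opposing_nt, "C"))
    nm <- nrow(parse_mutations(library$mutations[q]))
    c(active = if (acp$satisfiable) acp$probability else 0,
      sim = sim, num_mut = nm, site_ac = ac)
  }, numeric(4)))
}

#' Plant editing levels in a synthetic library
#'
#' The planted truth is `plogis(b + w1 * P_active + w2 * sim - w3 * n_mut +
#' w4 * ac_flag)` with the intercept `b` calibrated so the WT variant sits at
#' `wt_editing`; variants whose constrained fold is unsatisfiable contribute
#' `P_active = 0` (core unformable, biologically inactive) while their
#' feature value stays missing for the model. Replicates are truth plus
#' Gaussian noise, clamped to `[0, 1]`.
#'
#' @param library a `variant_library`.
#' @param sub the [substrate()].
#' @param spec the [synth_spec()] (weights, noise, replicate count, seed).
#' @param model [energy_model()].
#' @return the library with `rep1..repK`, `mean_editing`, `zscore`, and
#'   `true_editing` columns added.
#' @export
plant_editing <- function(library, sub, spec, model = energy_model()) {
  drv <- planted_drivers(library, sub, model)
  w <- spec$weights
  eta <- w[["active_conf"]] * drv[, "active"] + w[["sim"]] * drv[, "sim"] -
    w[["num_mut"]] * drv[, "num_mut"] + w[["site_ac"]] * drv[, "site_ac"]
  wt_row <- which(library$mutations == "")[1]
  b <- stats::qlogis(spec$wt_editing) - eta[wt_row]
  truth <- stats::plogis(b + eta)
  set.seed(spec$seed + 2L)
  reps <- matrix(pmin(1, pmax(0, truth + rnorm(length(truth) * spec$n_reps,
                                               0, spec$noise_sd))),
                 nrow = length(truth))
  colnames(reps) <- paste0("rep", seq_len(spec$n_reps))
  out <- cbind(library, reps,
               data.frame(true_editing = truth,
                          mean_editing = rowMeans(reps)))
  out$zscore <- zscore_library(out$mean_editing, out$mean_editing[wt_row])
  new_variant_library(out)
}

#' Simulate amplicon reads for one variant
#'
#' Draws `Binomial(coverage, editing)` edited reads carrying G at the
#' editing site (A otherwise), then applies uniform per-base substitution
#' errors.
#'
#' @param sequence variant sequence.
#' @param site editing-site position in the variant's coordinates.
#' @param coverage number of reads.
#' @param editing true editing fraction.
#' @param error_rate per-base error probability.
#' @return character vector of read sequences.
#' @export
gen_reads <- function(sequence, site, coverage, editing, error_rate = 0) {
  stopifnot(coverage >= 1)
  n_ed <- rbinom(1, coverage, editing)
  edited <- sequence
  substr(edited, site, site) <- "G"
  reads <- c(rep(edited, n_ed), rep(sequence, coverage - n_ed))
  if (error_rate > 0) {
    nts <- c("A", "C", "G", "U")
    len <- nchar(sequence)
    nerr <- rbinom(1, coverage * len, error_rate)
    if (nerr > 0) {
      ri <- sample(coverage, nerr, TRUE)
      pi <- sample(len, nerr, TRUE)
      for (q in seq_len(nerr)) {
        old <- substr(reads[ri[q]], pi[q], pi[q])
        substr(reads[ri[q]], pi[q], pi[q]) <- sample(setdiff(nts, old), 1)
      }
    }
  }
  reads
}

#' Write reads as FASTQ
#'
#' @param reads character vector of read sequences.
#' @param path output file.
#' @param prefix read-name prefix.
#' @return the path, invisibly.
#' @export
write_fastq <- function(reads, path, prefix = "read") {
  x <- Biostrings::BStringSet(reads)
  names(x) <- sprintf("%s%06d", prefix, seq_along(reads))
  Biostrings::writeXStringSet(x, path, format = "fastq",
                              qualities = Biostrings::BStringSet(
                                vapply(nchar(reads), function(l)
                                  strrep("I", l), character(1))))
  invisible(path)
}
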