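#' Define an editing substrate
#'
#' A substrate is the folded RNA molecule carrying one editing site: the WT
#' sequence, the 1-based editing-site index (which must be an A), the ECS
#' region if known, the substrate-level constraint and reference strings used
#' by the active-conformation probability, and the WT MFE structure.
#'
#' @param name substrate identifier.
#' @param wt_sequence WT RNA sequence.
#' @param editing_site 1-based index of the edited adenosine.
#' @param ecs_region optional `c(start, end)` of the editing complementary
#'   sequence.
#' @param constraint optional constraint string (see [fold_mfe()]).
#' @param reference optional reference dot-bracket marking the required core.
#' @param wt_structure optional WT MFE dot-bracket; computed with the builtin
#'   engine when absent.
#' @param model [energy_model()] used when folding is needed.
#' @return object of class `substrate`.
#' @export
substrate <- function(name, wt_sequence, editing_site, ecs_region = NULL,
                      constraint = NULL, reference = NULL,
                      wt_structure = NULL, model = energy_model()) {
  wt_sequence <- toupper(gsub("T", "U", wt_sequence, fixed = TRUE))
  n <- nchar(wt_sequence)
  if (substr(wt_sequence, editing_site, editing_site) != "A")
    stop("editing site must be an A")
  for (s in list(constraint, reference, wt_structure))
    if (!is.null(s) && nchar(s) != n)
      stop("constraint/reference/structure length must match the sequence")
  if (is.null(wt_structure))
    wt_structure <- fold_mfe(wt_sequence, model)$structure
  structure(list(name = name, wt_sequence = wt_sequence,
                 editing_site = as.integer(editing_site),
                 ecs_region = ecs_region, constraint = constraint,
                 reference = reference, wt_structure = wt_structure),
            class = "substrate")
}

#' @export
print.substrate <- function(x, ...) {
  cat("Substrate", x$name, "(", nchar(x$wt_sequence), "nt, editing site",
      x$editing_site, ")\n")
  cat(" ", x$wt_sequence, "\n ", x$wt_structure, "\n")
  invisible(x)
}

PURINES <- c("A", "G")

#' Parse a mutation descriptor string
#'
#' Descriptors are `;`-separated items: `pos:ref>alt` for a substitution,
#' `pos:ins:SEQ` for an insertion of SEQ after `pos`, `pos:del:k` for a
#' deletion of `k` nucleotides starting at `pos`. An empty string is the WT
#' (no mutations).
#'
#' @param mutations descriptor string.
#' @return data.frame with columns `pos`, `type` (sub/ins/del), `ref`, `alt`.
#' @export
parse_mutations <- function(mutations) {
  if (is.na(mutations) || mutations == "")
    return(data.frame(pos = integer(), type = character(),
                      ref = character(), alt = character(),
                      stringsAsFactors = FALSE))
  items <- strsplit(mutations, ";", fixed = TRUE)[[1]]
  out <- lapply(items, function(it) {
    f <- strsplit(it, ":", fixed = TRUE)[[1]]
    if (length(f) == 2 && grepl(">", f[2], fixed = TRUE)) {
      ra <- strsplit(f[2], ">", fixed = TRUE)[[1]]
      data.frame(pos = as.integer(f[1]), type = "sub", ref = ra[1],
                 alt = ra[2], stringsAsFactors = FALSE)
    } else if (length(f) == 3 && f[2] == "ins") {
      data.frame(pos = as.integer(f[1]), type = "ins", ref = "",
                 alt = f[3], stringsAsFactors = FALSE)
    } else if (length(f) == 3 && f[2] == "del") {
      data.frame(pos = as.integer(f[1]), type = "del", ref = f[3],
                 alt = "", stringsAsFactors = FALSE)
    } else stop("malformed mutation item: ", it)
  })
  do.call(rbind, out)
}

format_mutations <- function(mut) {
  if (!nrow(mut)) return("")
  paste(vapply(seq_len(nrow(mut)), function(q) {
    m <- mut[q, ]
    switch(m$type,
           sub = paste0(m$pos, ":", m$ref, ">", m$alt),
           ins = paste0(m$pos, ":ins:", m$alt),
           del = paste0(m$pos, ":del:", m$ref))
  }, character(1)), collapse = ";")
}

#' Apply mutations to a WT sequence
#'
#' @param wt_sequence WT sequence.
#' @param mutations descriptor string (see [parse_mutations()]).
#' @return mutated sequence.
#' @export
apply_mutations <- function(wt_sequence, mutations) {
  mut <- parse_mutations(mutations)
  if (!nrow(mut)) return(wt_sequence)
  v <- strsplit(wt_sequence, "")[[1]]
  subs <- mut[mut$type == "sub", , drop = FALSE]
  for (q in seq_len(nrow(subs))) {
    m <- subs[q, ]
    if (v[m$pos] != m$ref)
      stop("reference mismatch at position ", m$pos, ": expected ", m$ref,
           ", sequence has ", v[m$pos])
    v[m$pos] <- m$alt
  }
  indels <- mut[mut$type != "sub", , drop = FALSE]
  indels <- indels[order(-indels$pos), , drop = FALSE]  # right to left
  for (q in seq_len(nrow(indels))) {
    m <- indels[q, ]
    if (m$type == "ins") {
      v <- append(v, strsplit(m$alt, "")[[1]], after = m$pos)
    } else {
      k <- as.integer(m$ref)
      v <- v[-(m$pos:(m$pos + k - 1L))]
    }
  }
  paste(v, collapse = "")
}

#' Position of the editing site in a variant's coordinates
#'
#' Indels 5' of the editing site shift it; substitutions never do.
#'
#' @param sub a [substrate()].
#' @param mutations descriptor string.
#' @return 1-based editing-site index in the variant sequence.
#' @export
variant_editing_site <- function(sub, mutations) {
  mut <- parse_mutations(mutations)
  pos <- sub$editing_site
  for (q in seq_len(nrow(mut))) {
    m <- mut[q, ]
    if (m$type == "ins" && m$pos < pos) pos <- pos + nchar(m$alt)
    if (m$type == "del" && m$pos <= pos) pos <- pos - as.integer(m$ref)
  }
  pos
}

new_variant_library <- function(df) {
  rownames(df) <- NULL
  class(df) <- c("variant_library", "data.frame")
  df
}

#' Enumerate designed variants of a substrate
#'
#' Produces the deduplicated variant set for a mutagenesis design: all
#' single substitutions over the named regions (3 per position, editing site
#' excluded), optional double transversions, compensatory stem doubles that
#' swap a WT pair for another canonical pair, and explicit indels.
#'
#' @param sub a [substrate()].
#' @param design list with any of:
#'   `regions` (list of `c(start, end)` windows for singles),
#'   `exclude` (data.frame `pos`/`ref`/`alt` of forbidden substitutions,
#'   e.g. A>G at the -1/+1 positions, indistinguishable from editing),
#'   `double_pairs` (list of position pairs for double transversions),
#'   `compensatory_pairs` (list of WT base-pair positions `c(i, j)` to swap),
#'   `indels` (character vector of indel descriptor strings).
#' @return a `variant_library` data.frame with columns `id`, `mutations`,
#'   `sequence` (the WT row is included with an empty descriptor).
#' @export
enumerate_designed_variants <- function(sub, design) {
  wt <- sub$wt_sequence
  v <- strsplit(wt, "")[[1]]
  nts <- c("A", "C", "G", "U")
  muts <- character(0)

  excl <- design$exclude
  is_excluded <- function(pos, ref, alt) {
    if (is.null(excl)) return(FALSE)
    any(excl$pos == pos & excl$ref == ref & excl$alt == alt)
  }
  transversions <- function(ref)
    if (ref %in% PURINES) setdiff(nts, PURINES) else PURINES

  for (rg in design$regions) {
    if (rg[1] < 1 || rg[2] > nchar(wt)) stop("region outside sequence")
    for (p in rg[1]:rg[2]) {
      if (p == sub$editing_site) next
      for (alt in setdiff(nts, v[p]))
        if (!is_excluded(p, v[p], alt))
          muts <- c(muts, paste0(p, ":", v[p], ">", alt))
    }
  }
  for (pp in design$double_pairs) {
    a1 <- transversions(v[pp[1]])[1]
    a2 <- transversions(v[pp[2]])[1]
    muts <- c(muts, paste0(pp[1], ":", v[pp[1]], ">", a1, ";",
                           pp[2], ":", v[pp[2]], ">", a2))
  }
  for (pp in design$compensatory_pairs) {
    i <- pp[1]; j <- pp[2]
    swapped <- c(v[j], v[i])  # reverse the pair: always canonical again
    if (!identical(swapped, c(v[i], v[j])))
      muts <- c(muts, paste0(i, ":", v[i], ">", swapped[1], ";",
                             j, ":", v[j], ">", swapped[2]))
  }
  muts <- c(muts, unlist(design$indels))
  muts <- unique(muts)
  seqs <- vapply(muts, function(m) apply_mutations(wt, m), character(1))
  new_variant_library(data.frame(
    id = c("WT", sprintf("var%03d", seq_along(muts))),
    mutations = c("", muts),
    sequence = c(wt, unname(seqs)),
    stringsAsFactors = FALSE))
}

#' Library Z-score standardization
#'
#' Standardizes per-variant editing levels against the WT level:
#' `Z_i = (EL_i - EL_WT) / S` where `S` is the population standard deviation
#' of the deviations `x_i = EL_i - EL_WT` over the library,
#' `S = sqrt(sum((x_i - mean(x))^2) / N)`. The WT variant scores exactly 0.
#'
#' @param editing_levels numeric vector of per-variant mean editing levels.
#' @param el_wt the WT variant's mean editing level.
#' @return numeric vector of Z-scores.
#' @export
zscore_library <- function(editing_levels, el_wt) {
  if (length(editing_levels) < 2L) stop("need at least 2 variants")
  x <- editing_levels - el_wt
  s <- sqrt(mean((x - mean(x))^2))
  if (s == 0) stop("degenerate library: all editing levels identical")
  x / s
}

#' Classify a single substitution by sequence and structural outcome
#'
#' The six-way taxonomy: the sequence label is `transition`
#' (purine-to-purine or pyrimidine-to-pyrimidine) or `transversion`; the
#' structural suffix is empty when WT and variant pair tables are identical,
#' `+break` when the only change is loss of the pair at the mutation site,
#' and `+shift` for every other pair-table change (new pairs, or more than
#' one pair lost).
#'
#' @param pos,ref,alt the substitution.
#' @param wt_structure,variant_structure MFE dot-brackets of WT and variant
#'   (same length).
#' @return one of `"transition"`, `"transversion"`, `"transition+break"`,
#'   `"transversion+break"`, `"transition+shift"`, `"transversion+shift"`.
#' @export
classify_mutation <- function(pos, ref, alt, wt_structure, variant_structure) {
  if (nchar(wt_structure) != nchar(variant_structure))
    stop("classification is defined for single substitutions only")
  base <- if ((ref %in% PURINES) == (alt %in% PURINES))
    "transition" else "transversion"
  wt_pt <- parse_dotbracket(wt_structure)$partner
  var_pt <- parse_dotbracket(variant_structure)$partner
  diffs <- which(wt_pt != var_pt)
  if (!length(diffs)) return(base)
  wp <- wt_pt[pos]
  if (wp > 0L && var_pt[pos] == 0L && setequal(diffs, c(pos, wp)) &&
      var_pt[wp] == 0L)
    return(paste0(base, "+break"))
  paste0(base, "+shift")
}

#' Assign sequencing reads to library variants and quantify editing
#'
#' A read is assigned iff, after masking the variant's editing-site
#' position, it exactly matches exactly one variant's full sequence
#' signature (the desk-scale substitute for the mapper-based assignment;
#' no error correction is attempted). The editing level of a variant is
#' G / (A + G) at its editing site among assigned reads.
#'
#' @param reads character vector of read sequences (or a
#'   `Biostrings::DNAStringSet`/`RNAStringSet`).
#' @param sub a [substrate()].
#' @param library a `variant_library` (needs `id`, `mutations`, `sequence`).
#' @param min_reads variants with fewer assigned reads are flagged
#'   `low_coverage`.
#' @return data.frame with `id`, `n_reads`, `n_edited`, `editing_level`,
#'   `low_coverage`.
#' @export
assign_reads_to_variants <- function(reads, sub, library, min_reads = 100L) {
  reads <- toupper(gsub("T", "U", as.character(reads), fixed = TRUE))
  site <- vapply(library$mutations, function(m) variant_editing_site(sub, m),
                 integer(1))
  sigs <- library$sequence
  substr(sigs, site, site) <- "N"
  if (anyDuplicated(sigs))
    stop("ambiguous design: variants ",
         paste(library$id[duplicated(sigs) | duplicated(sigs, fromLast = TRUE)],
               collapse = ", "),
         " are identical outside the editing site")
  n_reads <- integer(nrow(library))
  n_edited <- integer(nrow(library))
  n_unedited <- integer(nrow(library))
  lens <- nchar(reads)
  for (q in seq_len(nrow(library))) {
    cand <- which(lens == nchar(sigs[q]))
    if (!length(cand)) next
    masked <- reads[cand]
    substr(masked, site[q], site[q]) <- "N"
    hit <- cand[masked == sigs[q]]
    n_reads[q] <- length(hit)
    base <- substr(reads[hit], site[q], site[q])
    n_edited[q] <- sum(base == "G")
    n_unedited[q] <- sum(base == "A")
  }
  el <- ifelse(n_edited + n_unedited > 0,
               n_edited / (n_edited + n_unedited), NA_real_)
  data.frame(id = library$id, n_reads = n_reads, n_edited = n_edited,
             editing_level = el, low_coverage = n_reads < min_reads,
             stringsAsFactors = FALSE)
}

#' Read / write a variant library TSV
#'
#' Tab-separated with documented columns `id`, `mutations`, `sequence`,
#' replicate columns `rep1..repK`, `mean_editing`, `zscore`. Round-trips all
#' fields losslessly.
#'
#' @param path file path.
#' @param library a `variant_library` data.frame.
#' @return `read_library`: a `variant_library`.
#' @export
read_library <- function(path) {
  first <- readLines(path, n = 1L)
  if (!length(first)) {
    warning("empty library file: ", path)
    return(new_variant_library(data.frame(id = character(),
                                          mutations = character(),
                                          sequence = character(),
                                          stringsAsFactors = FALSE)))
  }
  df <- read.delim(path, stringsAsFactors = FALSE, colClasses = NA,
                   na.strings = "NA")
  needed <- c("id", "mutations", "sequence")
  if (!all(needed %in% names(df)))
    stop("library file lacks required columns: ",
         paste(setdiff(needed, names(df)), collapse = ", "))
  df$mutations[is.na(df$mutations)] <- ""
  bad <- which(is.na(df$id) | is.na(df$sequence))
  if (length(bad))
    stop("malformed library row(s) at line(s): ",
         paste(bad + 1L, collapse = ", "))
  new_variant_library(df)
}

#' @rdname read_library
#' @export
write_library <- function(library, path) {
  write.table(library, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
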