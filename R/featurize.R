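ELEMENT_KINDS <- c("stem", "hairpin", "internal", "bulge", "multiloop",
                   "exterior")
CANONICAL_PAIRS <- c("G:C", "C:G", "A:U", "U:A", "G:U", "U:G")
NT_LEVELS <- c("A", "C", "G", "U")

nt_code <- function(x) {
  out <- match(x, NT_LEVELS)
  out[is.na(x)] <- NA_integer_
  out
}
pair_code <- function(x) {
  out <- match(x, CANONICAL_PAIRS)
  out[!is.na(x) & is.na(out)] <- 7L  # noncanonical
  out[is.na(x)] <- 0L                # no closing pair
  out
}

elem_feature_names <- function(prefix) {
  c(paste0(prefix, "_elem:", ELEMENT_KINDS),
    paste0(prefix, c("_dim5", "_dim3", "_cp5_pair", "_cp3_pair")),
    paste0(prefix, "_5prm_cp_internal:", CANONICAL_PAIRS),
    paste0(prefix, "_3prm_cp_internal:", CANONICAL_PAIRS))
}

#' The versioned feature registry
#'
#' Ordered list of every feature the matrix builder can emit, its high-level
#' group (one of nine), and its kind (`numeric`, `onehot`, `boolean`).
#' Categorical features are one-hot encoded with `feature:VALUE` names
#' (e.g. `site_1_1:A:C`, `d2_5prm_cp_internal:G:C`); the -1/+1 nucleotide
#' features `site_prev_nt`/`site_next_nt` and closing-pair identities are
#' integer-coded (A=1..U=4; pairs G:C=1..U:G=6, 7=noncanonical, 0=absent).
#'
#' @return data.frame with columns `name`, `group`, `kind`; attribute
#'   `version`.
#' @export
feature_registry <- function() {
  rows <- list()
  add <- function(names, group, kind)
    rows[[length(rows) + 1L]] <<- data.frame(name = names, group = group,
                                             kind = kind,
                                             stringsAsFactors = FALSE)
  add(c("mfe", "ensemble_energy", "mfe_frequency", "ensemble_diversity",
        "all_stem_length", "probability_active_conf", "sim_nor_score"),
      "structure", "numeric")
  add("num_mutations", "num_mutations", "numeric")
  add(c("mut_pos", "dist_to_site"), "mutation_sequence", "numeric")
  add(c(paste0("mut_ref:", NT_LEVELS), paste0("mut_alt:", NT_LEVELS)),
      "mutation_sequence", "onehot")
  add(c(paste0("mut_elem:", ELEMENT_KINDS),
        paste0("mut_up_elem:", ELEMENT_KINDS),
        paste0("mut_down_elem:", ELEMENT_KINDS)),
      "mutation_structure", "onehot")
  add("same_elem_as_site", "mutation_structure", "boolean")
  add(c("mut_type:SNP", "mut_type:indel"), "mutation_other", "onehot")
  add("is_mutated", "mutation_other", "boolean")
  add(c("site_prev_nt", "site_next_nt", "site_opposing_nt"),
      "site_sequence", "numeric")
  site <- elem_feature_names("site")
  add(site[grepl(":", site, fixed = TRUE)], "site_structure", "onehot")
  add(site[!grepl(":", site, fixed = TRUE)], "site_structure", "numeric")
  add("site_1_1:A:C", "site_structure", "boolean")
  for (pre in c("u1", "u2")) {
    nm <- elem_feature_names(pre)
    add(nm[grepl(":", nm, fixed = TRUE)], "upstream_context", "onehot")
    add(nm[!grepl(":", nm, fixed = TRUE)], "upstream_context", "numeric")
  }
  for (pre in c("d1", "d2", "d3")) {
    nm <- elem_feature_names(pre)
    add(nm[grepl(":", nm, fixed = TRUE)], "downstream_context", "onehot")
    add(nm[!grepl(":", nm, fixed = TRUE)], "downstream_context", "numeric")
  }
  reg <- do.call(rbind, rows)
  stopifnot(!anyDuplicated(reg$name))
  attr(reg, "version") <- "1"
  reg
}

# features of one structural element under a name prefix; NULL = absent flank
elem_features <- function(el, prefix) {
  nm <- elem_feature_names(prefix)
  v <- setNames(rep(NA_real_, length(nm)), nm)
  if (is.null(el)) return(v)
  v[paste0(prefix, "_elem:", ELEMENT_KINDS)] <-
    as.numeric(ELEMENT_KINDS == el$kind)
  d <- el$dims
  v[paste0(prefix, "_dim5")] <- d[1]
  v[paste0(prefix, "_dim3")] <- if (length(d) > 1) d[2] else d[1]
  v[paste0(prefix, "_cp5_pair")] <- pair_code(el$closing5)
  v[paste0(prefix, "_cp3_pair")] <- pair_code(el$closing3)
  is_int <- el$kind == "internal"
  v[paste0(prefix, "_5prm_cp_internal:", CANONICAL_PAIRS)] <-
    as.numeric(is_int & CANONICAL_PAIRS == ifelse(is.na(el$closing5), "",
                                                  el$closing5))
  v[paste0(prefix, "_3prm_cp_internal:", CANONICAL_PAIRS)] <-
    as.numeric(is_int & CANONICAL_PAIRS == ifelse(is.na(el$closing3), "",
                                                  el$closing3))
  v
}

#' Build the feature vector for one mutated base of one variant
#'
#' @param variant one-row slice of a `variant_library` (id, mutations,
#'   sequence).
#' @param mut_index which mutation of the variant this row describes (0 for
#'   the WT row).
#' @param sub the [substrate()].
#' @param fold a `fold_result` for the variant (or `NULL` on fold failure).
#' @param active an `active_conf_result` (or `NULL`).
#' @param ctx a `site_context` for the variant (or `NULL`).
#' @param sim normalized structure-similarity score to WT (or `NA`).
#' @param elements the variant's `structure_elements` (or `NULL`).
#' @return named numeric vector aligned to [feature_registry()].
#' @export
build_feature_row <- function(variant, mut_index, sub, fold, active, ctx,
                              sim, elements = NULL) {
  reg <- feature_registry()
  v <- setNames(rep(NA_real_, nrow(reg)), reg$name)
  mut <- parse_mutations(variant$mutations)

  if (!is.null(fold)) {
    v["mfe"] <- fold$mfe_energy
    v["ensemble_energy"] <- fold$ensemble_energy
    v["mfe_frequency"] <- fold$mfe_frequency
    v["ensemble_diversity"] <- fold$ensemble_diversity
    if (!is.null(elements))
      v["all_stem_length"] <- stem_length_summary(elements)
  }
  if (!is.null(active) && isTRUE(active$satisfiable))
    v["probability_active_conf"] <- active$probability
  v["sim_nor_score"] <- sim
  v["num_mutations"] <- nrow(mut)
  v["is_mutated"] <- as.numeric(nrow(mut) > 0)

  if (!is.null(ctx)) {
    v["site_prev_nt"] <- nt_code(ctx$prev_nt)
    v["site_next_nt"] <- nt_code(ctx$next_nt)
    v["site_opposing_nt"] <- if (is.na(ctx$opposing_nt)) 0
                             else nt_code(ctx$opposing_nt)
    v[names(elem_features(ctx$site, "site"))] <- elem_features(ctx$site, "site")
    v["site_1_1:A:C"] <- as.numeric(ctx$site$kind == "internal" &&
                                    all(ctx$site$dims == c(1, 1)) &&
                                    identical(ctx$opposing_nt, "C"))
    for (slot in c("u1", "u2", "d1", "d2", "d3"))
      v[elem_feature_names(slot)] <- elem_features(ctx[[slot]], slot)
  }

  if (mut_index > 0L && mut_index <= nrow(mut)) {
    m <- mut[mut_index, ]
    v["mut_pos"] <- m$pos
    v["dist_to_site"] <- m$pos - sub$editing_site
    v[paste0("mut_ref:", NT_LEVELS)] <-
      as.numeric(m$type == "sub" & NT_LEVELS == m$ref)
    v[paste0("mut_alt:", NT_LEVELS)] <-
      as.numeric(m$type == "sub" & NT_LEVELS == m$alt)
    v["mut_type:SNP"] <- as.numeric(m$type == "sub")
    v["mut_type:indel"] <- as.numeric(m$type != "sub")
    if (!is.null(elements) && !is.null(ctx)) {
      # position in variant coordinates (indels 5' of it shift it)
      vpos <- m$pos
      for (q in seq_len(nrow(mut))) {
        mm <- mut[q, ]
        if (mm$type == "ins" && mm$pos < m$pos) vpos <- vpos + nchar(mm$alt)
        if (mm$type == "del" && mm$pos < m$pos)
          vpos <- vpos - min(as.integer(mm$ref), m$pos - mm$pos)
      }
      vpos <- max(1L, min(vpos, nchar(variant$sequence)))
      holds <- which(vapply(elements, function(e) vpos %in% e$positions,
                            logical(1)))
      if (length(holds) == 1L) {
        v[paste0("mut_elem:", ELEMENT_KINDS)] <-
          as.numeric(ELEMENT_KINDS == elements[[holds]]$kind)
        up <- if (holds > 1L) elements[[holds - 1L]]$kind else NA
        dn <- if (holds < length(elements)) elements[[holds + 1L]]$kind else NA
        v[paste0("mut_up_elem:", ELEMENT_KINDS)] <-
          if (is.na(up)) NA_real_ else as.numeric(ELEMENT_KINDS == up)
        v[paste0("mut_down_elem:", ELEMENT_KINDS)] <-
          if (is.na(dn)) NA_real_ else as.numeric(ELEMENT_KINDS == dn)
        v["same_elem_as_site"] <- as.numeric(holds == ctx$site_index)
      }
    }
  } else {
    v["mut_type:SNP"] <- 0
    v["mut_type:indel"] <- 0
  }
  v
}

#' Build the per-mutated-base feature matrix for a library
#'
#' One row per mutated base of every variant (the WT contributes a single
#' row with `num_mutations = 0`); rows ordered by library order then
#' mutation position. Fold failures leave a variant's structure features
#' missing rather than dropping the row.
#'
#' @param library a `variant_library` with `mean_editing` (and optionally
#'   replicate columns).
#' @param sub the [substrate()].
#' @param model [energy_model()].
#' @param backend folding backend for [external_fold_adapter()].
#' @param edited_threshold editing level above which the binary label is 1.
#' @return object of class `feature_matrix`: list with `features` (numeric
#'   matrix, columns = registry names), `meta` (variant id, row position,
#'   target, label), `registry`.
#' @export
build_matrix <- function(library, sub, model = energy_model(),
                         backend = "builtin", edited_threshold = 0.01) {
  reg <- feature_registry()
  wt_tree <- to_tree(annotate_elements(parse_dotbracket(sub$wt_structure),
                                       sub$wt_sequence))
  rows <- list(); meta <- list()
  for (q in seq_len(nrow(library))) {
    variant <- library[q, ]
    seqn <- variant$sequence
    fold <- tryCatch(external_fold_adapter(seqn, backend = backend,
                                           model = model),
                     error = function(e) NULL)
    elements <- NULL; ctx <- NULL; sim <- NA_real_
    if (!is.null(fold)) {
      elements <- annotate_elements(parse_dotbracket(fold$mfe_structure), seqn)
      es <- variant_editing_site(sub, variant$mutations)
      ctx <- tryCatch(locate_site_context(elements, es, seqn),
                      error = function(e) NULL)
      sim <- similarity_score(to_tree(elements), wt_tree)
    }
    active <- tryCatch(
      active_conformation_probability(seqn, model, sub$constraint,
                                      sub$reference),
      error = function(e) NULL)
    nmut <- nrow(parse_mutations(variant$mutations))
    idxs <- if (nmut == 0L) 0L else seq_len(nmut)
    for (mi in idxs) {
      rows[[length(rows) + 1L]] <-
        build_feature_row(variant, mi, sub, fold, active, ctx, sim, elements)
      pos <- if (mi == 0L) 0L else parse_mutations(variant$mutations)$pos[mi]
      meta[[length(meta) + 1L]] <-
        data.frame(variant_id = variant$id, position = pos,
                   target = if ("mean_editing" %in% names(variant))
                     variant$mean_editing else NA_real_,
                   stringsAsFactors = FALSE)
    }
  }
  features <- do.call(rbind, rows)
  meta <- do.call(rbind, meta)
  meta$label <- as.numeric(meta$target > edited_threshold)
  ord <- order(match(meta$variant_id, library$id), meta$position)
  structure(list(features = features[ord, , drop = FALSE],
                 meta = meta[ord, , drop = FALSE], registry = reg),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat("feature_matrix:", nrow(x$features), "rows x", ncol(x$features),
      "features (registry v", attr(x$registry, "version"), ")\n")
  invisible(x)
}

#' Drop null / non-varying features based on the training split
#'
#' The mask is computed on training rows only (a feature is dropped when it
#' is entirely missing there, or its non-missing values are constant) and
#' then applied to every split.
#'
#' @param fm a `feature_matrix`.
#' @param splits a `split_assignment` (see [make_position_splits()]).
#' @return the masked `feature_matrix`, with attribute `dropped`.
#' @export
apply_split_masks <- function(fm, splits) {
  row_split <- assign_rows(fm, splits)
  train <- which(row_split == "train")
  if (!length(train)) stop("empty training split")
  keep <- vapply(seq_len(ncol(fm$features)), function(j) {
    v <- fm$features[train, j]
    v <- v[!is.na(v)]
    length(v) > 0L && length(unique(v)) > 1L
  }, logical(1))
  dropped <- colnames(fm$features)[!keep]
  fm$features <- fm$features[, keep, drop = FALSE]
  fm$registry <- fm$registry[fm$registry$name %in% colnames(fm$features), ]
  attr(fm, "dropped") <- dropped
  fm
}
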