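#' Hierarchical clustering of variants by structure
#'
#' A documented simplified substitute for sequence-structure alignment
#' pipelines: pairwise distance `1 - similarity_score` between element
#' trees, average-linkage agglomeration, a Newick dendrogram, and
#' per-cluster summaries (consensus element-kind string by majority, mean
#' and sd of editing).
#'
#' @param library a `variant_library` with `mean_editing`.
#' @param structures character vector of dot-bracket MFE structures, one per
#'   variant (folded on demand if `NULL`).
#' @param k number of clusters to cut.
#' @param model [energy_model()] for on-demand folding.
#' @return list with `clusters` (data.frame id/cluster), `newick`,
#'   `summary` (per-cluster consensus element string, mean/sd editing),
#'   `hclust`.
#' @export
cluster_variants <- function(library, structures = NULL, k = 2L,
                             model = energy_model()) {
  n <- nrow(library)
  if (n < 2L) stop("need at least 2 variants to cluster")
  if (is.null(structures))
    structures <- vapply(library$sequence, function(s)
      fold_mfe(s, model)$structure, character(1))
  if (k > n) stop("fewer structures than requested clusters")
  trees <- lapply(seq_len(n), function(q)
    to_tree(annotate_elements(parse_dotbracket(structures[q]),
                              library$sequence[q])))
  elem_strings <- vapply(seq_len(n), function(q) {
    els <- annotate_elements(parse_dotbracket(structures[q]),
                             library$sequence[q])
    paste(vapply(els, function(e) substr(e$kind, 1, 1), character(1)),
          collapse = "")
  }, character(1))
  d <- matrix(0, n, n)
  for (a in seq_len(n - 1)) for (b in (a + 1):n) {
    d[a, b] <- d[b, a] <- 1 - similarity_score(trees[[a]], trees[[b]])
  }
  rownames(d) <- colnames(d) <- library$id
  hc <- hclust(as.dist(d), method = "average")
  cl <- cutree(hc, k = k)
  phylo <- ape::as.phylo(hc)
  newick <- ape::write.tree(phylo)
  summ <- do.call(rbind, lapply(sort(unique(cl)), function(cc) {
    idx <- which(cl == cc)
    cons <- names(sort(table(elem_strings[idx]), decreasing = TRUE))[1]
    data.frame(cluster = cc, n = length(idx), consensus_elements = cons,
               mean_editing = if ("mean_editing" %in% names(library))
                 mean(library$mean_editing[idx]) else NA_real_,
               sd_editing = if ("mean_editing" %in% names(library))
                 sd(library$mean_editing[idx]) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  list(clusters = data.frame(id = library$id, cluster = unname(cl),
                             stringsAsFactors = FALSE),
       newick = newick, summary = summ, hclust = hc)
}

default_config <- function() {
  list(seed = 1L, backend = "builtin",
       split = list(fractions = c(train = 0.7, validation = 0.15,
                                  test = 0.15)),
       train = list(max_rounds = 1000L, patience = 10L,
                    objective = "regression"),
       edited_threshold = 0.01,
       cluster_k = 2L)
}

#' Run the full pipeline
#'
#' Executes the stages in order — (quantify from reads when FASTQ input is
#' given) — fold — annotate — featurize — split — train — evaluate —
#' explain — cluster — and writes every artifact plus a run manifest to
#' `out_dir`. With `config$synthetic = TRUE` (or a `synth_spec` in
#' `config$synth`), inputs are generated in-process.
#'
#' @param config list (or path to a JSON file): fields `substrate_fasta` +
#'   `substrate` (editing_site, constraint, reference) and `library_tsv`,
#'   or `synthetic`/`synth`; plus `seed`, `backend`, `split`, `train`,
#'   `edited_threshold`, `cluster_k`.
#' @param out_dir output directory (created).
#' @return list of artifacts (invisible); side effect: files + manifest.
#' @export
run_pipeline <- function(config, out_dir) {
  t0 <- Sys.time()
  if (is.character(config)) config <- jsonlite::read_json(config,
                                                          simplifyVector = TRUE)
  config <- modifyList(default_config(), config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  timings <- list(); warnings_log <- character(0)
  stage <- function(name, expr) {
    ts <- Sys.time()
    res <- tryCatch(expr, error = function(e)
      stop("[stage ", name, "] ", conditionMessage(e), call. = FALSE))
    timings[[name]] <<- as.numeric(difftime(Sys.time(), ts, units = "secs"))
    message(sprintf("[%s] done in %.2fs", name, timings[[name]]))
    res
  }

  inputs <- stage("inputs", {
    if (isTRUE(config$synthetic) || !is.null(config$synth)) {
      spec <- do.call(synth_spec, c(list(seed = config$seed),
                                    config$synth %||% list()))
      sub <- gen_substrate(spec)
      lib <- plant_editing(gen_library(sub, spec), sub, spec)
      list(sub = sub, lib = lib, spec = spec)
    } else {
      if (is.null(config$substrate_fasta))
        stop("config$substrate_fasta is required for non-synthetic runs")
      if (!file.exists(config$substrate_fasta))
        stop("config$substrate_fasta file not found: ",
             config$substrate_fasta)
      seqs <- Biostrings::readBStringSet(config$substrate_fasta)
      sc <- config$substrate
      if (is.null(sc$editing_site))
        stop("config$substrate$editing_site is required")
      sub <- substrate(names(seqs)[1], as.character(seqs[[1]]),
                       sc$editing_site, constraint = sc$constraint,
                       reference = sc$reference)
      if (is.null(config$library_tsv))
        stop("config$library_tsv is required")
      lib <- read_library(config$library_tsv)
      list(sub = sub, lib = lib)
    }
  })
  sub <- inputs$sub; lib <- inputs$lib

  fm <- stage("featurize", build_matrix(lib, sub, backend = config$backend,
                                        edited_threshold =
                                          config$edited_threshold))
  splits <- stage("split", {
    muts <- lapply(lib$mutations, parse_mutations)
    positions <- unique(unlist(lapply(muts, `[[`, "pos")))
    groups <- Filter(function(g) length(g) > 1,
                     lapply(muts, function(m) unique(m$pos)))
    make_position_splits(positions, groups,
                         fractions = config$split$fractions,
                         seed = config$seed)
  })
  assert_no_leakage(fm, splits)
  fm_masked <- stage("mask", apply_split_masks(fm, splits))
  model <- stage("train", {
    tp <- do.call(train_params, c(config$train, list(seed = config$seed)))
    train_model(fm_masked, splits, tp)
  })
  metrics <- stage("evaluate", evaluate(model, fm_masked, splits))
  shap <- stage("explain", explain(model, fm_masked, splits))
  clust <- stage("cluster", {
    strs <- vapply(lib$sequence, function(s) fold_mfe(s)$structure,
                   character(1))
    cluster_variants(lib, strs, k = config$cluster_k)
  })

  stage("write", {
    write_library(lib, file.path(out_dir, "library.tsv"))
    utils::write.csv(cbind(fm_masked$meta, fm_masked$features),
                     file.path(out_dir, "feature_matrix.csv"),
                     row.names = FALSE)
    jsonlite::write_json(unclass(metrics),
                         file.path(out_dir, "metrics.json"),
                         auto_unbox = TRUE, digits = NA)
    utils::write.csv(shap$feature_importance,
                     file.path(out_dir, "shap_importance.csv"),
                     row.names = FALSE)
    writeLines(clust$newick, file.path(out_dir, "dendrogram.nwk"))
    utils::write.csv(clust$clusters, file.path(out_dir, "clusters.csv"),
                     row.names = FALSE)
  })

  manifest <- list(
    config = config,
    seed = config$seed,
    registry_version = attr(fm$registry, "version"),
    n_variants = nrow(lib), n_rows = nrow(fm$features),
    n_features_masked = ncol(fm_masked$features),
    input_digests = list(
      library = digest_file(file.path(out_dir, "library.tsv")),
      feature_matrix = digest_file(file.path(out_dir, "feature_matrix.csv"))),
    timings = timings, warnings = warnings_log,
    started = format(t0), finished = format(Sys.time()))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(substrate = sub, library = lib, matrix = fm_masked,
                 splits = splits, model = model, metrics = metrics,
                 shap = shap, clusters = clust, manifest = manifest))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

digest_file <- function(path) {
  unname(tools::md5sum(path))
}
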