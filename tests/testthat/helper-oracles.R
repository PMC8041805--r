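# Independent oracles and shared fixtures for the test suite.

# ---- independent ordered-forest edit distance (exponential recursion,
# deliberately a different algorithm from the Zhang-Shasha implementation)
forest_edit_oracle <- function(f1, f2, relabel = 1) {
  # forests are lists of nodes: list(label=, children=list(...))
  size <- function(f) if (!length(f)) 0L else
    sum(vapply(f, function(t) 1L + size(t$children), integer(1)))
  rec <- function(f1, f2) {
    if (!length(f1)) return(size(f2))
    if (!length(f2)) return(size(f1))
    t1 <- f1[[1]]; r1 <- f1[-1]
    t2 <- f2[[1]]; r2 <- f2[-1]
    del <- rec(c(t1$children, r1), f2) + 1
    ins <- rec(f1, c(t2$children, r2)) + 1
    sub <- rec(t1$children, t2$children) + rec(r1, r2) +
      (if (identical(t1$label, t2$label)) 0 else relabel)
    min(del, ins, sub)
  }
  rec(f1, f2)
}

# convert a structure_tree to the nested-list form used by the oracle
tree_as_nested <- function(tree, node = tree$root) {
  list(label = tree$labels[node],
       children = lapply(tree$children[[node]], function(c_)
         tree_as_nested(tree, c_)))
}

# build a structure_tree directly from a nested list (for synthetic trees)
nested_as_tree <- function(nested) {
  labels <- character(0); children <- list(); parent <- integer(0)
  add <- function(nd, par) {
    labels <<- c(labels, nd$label)
    children[[length(labels)]] <<- integer(0)
    parent <<- c(parent, par)
    me <- length(labels)
    for (ch in nd$children) {
      idx <- add(ch, me)
      children[[me]] <<- c(children[[me]], idx)
    }
    me
  }
  add(nested, 0L)
  structure(list(labels = labels, children = children, root = 1L,
                 parent = parent), class = "structure_tree")
}

# independent count of valid structures by a counting recursion (no
# enumeration, no energies) -- checks brute_force_fold's enumeration
count_structures_oracle <- function(sequence, min_hairpin = 3L) {
  s <- strsplit(gsub("T", "U", toupper(sequence), fixed = TRUE), "")[[1]]
  ok <- function(a, b) paste0(s[a], s[b]) %in%
    c("GC", "CG", "AU", "UA", "GU", "UG")
  memo <- new.env()
  cnt <- function(i, j) {
    if (i >= j) return(1)
    key <- paste(i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    total <- cnt(i + 1, j)  # i unpaired
    for (k in (i + min_hairpin + 1):j) {
      if (k > j) break
      if (ok(i, k)) total <- total + cnt(i + 1, k - 1) * cnt(k + 1, j)
    }
    memo[[key]] <- total
    total
  }
  cnt(1L, length(s))
}

random_rna <- function(n) paste(sample(c("A", "C", "G", "U"), n, TRUE),
                                collapse = "")

# ---- shared fixtures, built once per test run
fixture_env <- new.env()

small_spec <- function() synth_spec(seed = 42L, n_singles = 14L,
                                    n_doubles = 6L, n_indels = 2L)

fixture_substrate <- function() {
  if (is.null(fixture_env$sub)) fixture_env$sub <- gen_substrate(small_spec())
  fixture_env$sub
}

fixture_library <- function() {
  if (is.null(fixture_env$lib))
    fixture_env$lib <- plant_editing(gen_library(fixture_substrate(),
                                                 small_spec()),
                                     fixture_substrate(), small_spec())
  fixture_env$lib
}

fixture_matrix <- function() {
  if (is.null(fixture_env$fm))
    fixture_env$fm <- build_matrix(fixture_library(), fixture_substrate())
  fixture_env$fm
}

library_splits <- function(lib, seed = 1L) {
  muts <- lapply(lib$mutations, parse_mutations)
  pos <- unique(unlist(lapply(muts, `[[`, "pos")))
  groups <- Filter(function(g) length(g) > 1,
                   lapply(muts, function(m) unique(m$pos)))
  make_position_splits(pos, groups, seed = seed)
}
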