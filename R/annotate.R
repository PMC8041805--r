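#' Parse dot-bracket notation into a pair table
#'
#' @param structure dot-bracket string over `(`, `)`, `.`.
#' @return object of class `pair_table`: list with `partner` (1-based pairing
#'   partner per position, 0 = unpaired) and `n`.
#' @export
parse_dotbracket <- function(structure) {
  v <- strsplit(structure, "")[[1]]
  bad <- setdiff(unique(v), c("(", ")", "."))
  if (length(bad)) stop("illegal character(s) in structure: ",
                        paste(bad, collapse = ", "))
  n <- length(v)
  partner <- integer(n)
  stack <- integer(0)
  for (i in seq_len(n)) {
    if (v[i] == "(") stack <- c(stack, i)
    else if (v[i] == ")") {
      if (!length(stack)) stop("unbalanced brackets at position ", i)
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      partner[i] <- j
      partner[j] <- i
    }
  }
  if (length(stack)) stop("unbalanced brackets: ", length(stack),
                          " unclosed '('")
  structure(list(partner = partner, n = n), class = "pair_table")
}

#' @export
print.pair_table <- function(x, ...) {
  cat("pair_table of length", x$n, "with", sum(x$partner > 0) / 2, "pairs\n")
  invisible(x)
}

pair_string <- function(sequence, i, j) {
  if (is.null(sequence)) return(NA_character_)
  paste(substr(sequence, i, i), substr(sequence, j, j), sep = ":")
}

#' Annotate a structure with bpRNA-style typed elements
#'
#' Segments a (pseudoknot-free) secondary structure into stems, hairpin
#' loops, bulges, internal loops, multiloops and a single exterior element,
#' recording closing-pair identities for every loop-type element. Every
#' nucleotide belongs to exactly one element: paired nucleotides to stems,
#' unpaired ones to the loop (or exterior) that contains them.
#'
#' @param pt a [parse_dotbracket()] pair table.
#' @param sequence optional RNA string (same length); enables closing-pair
#'   and loop nucleotide identities.
#' @return object of class `structure_elements`: a list of elements, each a
#'   list with fields `kind`, `positions`, `dims`, `closing5`, `closing3`,
#'   `outer_pair`, `strand5`, `strand3`; ordered by first position.
#' @export
annotate_elements <- function(pt, sequence = NULL) {
  n <- pt$n
  partner <- pt$partner
  if (!is.null(sequence) && nchar(sequence) != n)
    stop("sequence length does not match structure")
  elements <- list()
  add <- function(el) elements[[length(elements) + 1L]] <<- el

  # --- stems: maximal runs of stacked pairs
  opens <- which(partner > seq_len(n))
  used <- rep(FALSE, n)
  for (i in opens) {
    if (used[i]) next
    j <- partner[i]
    run_i <- i
    while ((run_i + 1L) <= n && partner[run_i + 1L] == partner[run_i] - 1L &&
           partner[run_i + 1L] > run_i + 1L) run_i <- run_i + 1L
    len <- run_i - i + 1L
    pos <- c(i:run_i, partner[run_i]:j)
    used[i:run_i] <- TRUE
    add(list(kind = "stem", positions = sort(pos), dims = len,
             closing5 = pair_string(sequence, i, j),
             closing3 = pair_string(sequence, run_i, partner[run_i]),
             outer_pair = c(i, j),
             inner_pair = c(run_i, partner[run_i]),
             strand5 = i:run_i, strand3 = sort(partner[run_i]:j)))
  }

  # --- loops: one per pair (a,b) that does not stack directly inward
  for (a in opens) {
    b <- partner[a]
    if (a + 1L <= n && partner[a + 1L] == b - 1L) next  # stacked, interior of stem
    # direct children pairs inside (a, b)
    kids <- list()
    k <- a + 1L
    while (k < b) {
      if (partner[k] > k) {
        kids[[length(kids) + 1L]] <- c(k, partner[k])
        k <- partner[k] + 1L
      } else k <- k + 1L
    }
    unp <- setdiff((a + 1L):(b - 1L),
                   unlist(lapply(kids, function(p) p[1]:p[2])))
    if (length(kids) == 0L) {
      add(list(kind = "hairpin", positions = unp, dims = length(unp),
               closing5 = pair_string(sequence, a, b), closing3 = NA_character_,
               outer_pair = c(a, b), strand5 = unp, strand3 = integer(0)))
    } else if (length(kids) == 1L) {
      ka <- kids[[1]][1]; kb <- kids[[1]][2]
      s5 <- if (ka - 1L >= a + 1L) (a + 1L):(ka - 1L) else integer(0)
      s3 <- if (b - 1L >= kb + 1L) (kb + 1L):(b - 1L) else integer(0)
      kind <- if (length(s5) > 0L && length(s3) > 0L) "internal" else "bulge"
      add(list(kind = kind, positions = unp,
               dims = c(length(s5), length(s3)),
               closing5 = pair_string(sequence, a, b),
               closing3 = pair_string(sequence, ka, kb),
               outer_pair = c(a, b), strand5 = s5, strand3 = s3))
    } else {
      add(list(kind = "multiloop", positions = unp,
               dims = c(length(unp), length(kids)),
               closing5 = pair_string(sequence, a, b),
               closing3 = pair_string(sequence, kids[[1]][1], kids[[1]][2]),
               outer_pair = c(a, b),
               strand5 = unp, strand3 = integer(0)))
    }
  }

  # --- exterior: all unpaired positions outside every pair
  ext <- which(partner == 0L)
  ext <- ext[vapply(ext, function(p) {
    !any(opens < p & partner[opens] > p)
  }, logical(1))]
  outer_stems <- sum(vapply(elements, function(e) {
    e$kind == "stem" &&
      !any(opens < e$outer_pair[1] & partner[opens] > e$outer_pair[2])
  }, logical(1)))
  if (length(ext) > 0L || outer_stems != 1L) {
    add(list(kind = "exterior", positions = ext, dims = length(ext),
             closing5 = NA_character_, closing3 = NA_character_,
             outer_pair = c(0L, 0L), strand5 = ext, strand3 = integer(0)))
  }

  first_pos <- vapply(elements, function(e)
    if (length(e$positions)) min(e$positions) else 0L, numeric(1))
  structure(elements[order(first_pos)], class = "structure_elements")
}

#' @export
print.structure_elements <- function(x, ...) {
  for (e in x)
    cat(sprintf("%-9s dims=%-8s n=%d  cp5=%s\n", e$kind,
                paste(e$dims, collapse = ":"), length(e$positions),
                ifelse(is.na(e$closing5), "-", e$closing5)))
  invisible(x)
}

#' Rebuild the dot-bracket string from annotated elements
#'
#' Inverse of [annotate_elements()] (via the stems' pair content); used for
#' the round-trip invariant.
#'
#' @param elements a `structure_elements` list.
#' @param n structure length.
#' @return dot-bracket string.
#' @export
elements_to_dotbracket <- function(elements, n) {
  partner <- integer(n)
  for (e in elements) {
    if (e$kind != "stem") next
    i <- e$outer_pair[1]; j <- e$outer_pair[2]
    for (off in 0:(e$dims - 1L)) {
      partner[i + off] <- j - off
      partner[j - off] <- i + off
    }
  }
  pairs_to_dotbracket(partner)
}

#' Structural context of the editing site
#'
#' Identifies the element containing the editing site and walks the element
#' sequence (elements ordered by first position along the molecule) to
#' collect up to two upstream (`u1`, `u2`) and three downstream (`d1`, `d2`,
#' `d3`) elements, plus the -1/+1 nucleotides and the nucleotide opposite
#' the site (its Watson-Crick partner in a stem; the antiparallel-aligned
#' base of the other strand for an internal loop, e.g. the C of an A:C 1:1
#' mismatch).
#'
#' @param elements output of [annotate_elements()].
#' @param editing_pos 1-based position of the edited adenosine.
#' @param sequence RNA string.
#' @return object of class `site_context`; absent flanks are `NULL`.
#' @export
locate_site_context <- function(elements, editing_pos, sequence) {
  n <- nchar(sequence)
  if (editing_pos < 1L || editing_pos > n) stop("editing_pos out of range")
  holds <- vapply(elements, function(e) editing_pos %in% e$positions,
                  logical(1))
  site_idx <- which(holds)
  stopifnot(length(site_idx) == 1L)
  site <- elements[[site_idx]]

  opposing <- NA_character_
  if (site$kind == "stem") {
    # partner within the stem: mirror index
    arm5 <- site$strand5; arm3 <- site$strand3
    if (editing_pos %in% arm5) {
      off <- match(editing_pos, arm5)
      opposing <- substr(sequence, rev(arm3)[off], rev(arm3)[off])
    } else {
      off <- match(editing_pos, rev(arm3))
      opposing <- substr(sequence, arm5[off], arm5[off])
    }
  } else if (site$kind == "internal") {
    if (editing_pos %in% site$strand5) {
      off <- match(editing_pos, site$strand5)
      other <- rev(site$strand3)
    } else {
      off <- match(editing_pos, rev(site$strand3))
      other <- site$strand5
    }
    idx <- min(off, length(other))
    opposing <- substr(sequence, other[idx], other[idx])
  }

  pick <- function(i) if (i >= 1L && i <= length(elements)) elements[[i]] else NULL
  structure(list(
    site = site, site_index = site_idx,
    u1 = pick(site_idx - 1L), u2 = pick(site_idx - 2L),
    d1 = pick(site_idx + 1L), d2 = pick(site_idx + 2L),
    d3 = pick(site_idx + 3L),
    prev_nt = if (editing_pos > 1L)
      substr(sequence, editing_pos - 1L, editing_pos - 1L) else NA_character_,
    next_nt = if (editing_pos < n)
      substr(sequence, editing_pos + 1L, editing_pos + 1L) else NA_character_,
    opposing_nt = opposing), class = "site_context")
}

#' Ordered rooted tree view of a structure
#'
#' Nodes are structural elements labelled by kind and dims; parent-child
#' edges follow nesting (a stem's child is the loop it closes; a loop's
#' children are the stems branching from it). Root is the exterior element
#' when present, otherwise the single outermost stem.
#'
#' @param elements output of [annotate_elements()].
#' @return object of class `structure_tree`: list with `labels` and
#'   `children` (list of integer vectors), node 1 = root.
#' @export
to_tree <- function(elements) {
  m <- length(elements)
  stopifnot(m >= 1L)
  # parent of each element by enclosing-pair logic
  enclosing_pair_of <- function(e) {
    # the pair directly enclosing this element's outer pair (stems) or the
    # element's own closing pair (loops)
    if (e$kind %in% c("hairpin", "internal", "bulge", "multiloop"))
      return(e$outer_pair)
    c(0L, 0L)
  }
  parent <- integer(m)
  for (q in seq_len(m)) {
    e <- elements[[q]]
    if (e$kind == "exterior") { parent[q] <- 0L; next }
    if (e$kind == "stem") {
      # parent is the loop (or exterior) whose region directly contains the
      # stem's outer pair
      i <- e$outer_pair[1]
      best <- 0L; best_span <- Inf
      for (r in seq_len(m)) {
        if (r == q) next
        f <- elements[[r]]
        if (f$kind == "stem") next
        if (f$kind == "exterior") next
        a <- f$outer_pair[1]; b <- f$outer_pair[2]
        if (a < i && b > e$outer_pair[2] && (b - a) < best_span) {
          best <- r; best_span <- b - a
        }
      }
      parent[q] <- best
    } else {
      # loop's parent is the stem whose innermost pair is its closing pair
      for (r in seq_len(m)) {
        f <- elements[[r]]
        if (f$kind == "stem" && f$inner_pair[1] == e$outer_pair[1] &&
            f$inner_pair[2] == e$outer_pair[2]) { parent[q] <- r; break }
      }
    }
  }
  ext <- which(vapply(elements, function(e) e$kind == "exterior", logical(1)))
  root <- if (length(ext)) ext else which(parent == 0L)
  stopifnot(length(root) == 1L)
  parent[parent == 0L & seq_len(m) != root] <- root
  # order: nodes re-indexed so traversal is deterministic (by first position)
  labels <- vapply(elements, function(e)
    paste0(e$kind, "[", paste(e$dims, collapse = ":"), "]"), character(1))
  children <- lapply(seq_len(m), function(q) which(parent == q))
  structure(list(labels = labels, children = children, root = root,
                 parent = parent), class = "structure_tree")
}

#' @export
print.structure_tree <- function(x, ...) {
  rec <- function(q, depth) {
    cat(strrep("  ", depth), x$labels[q], "\n", sep = "")
    for (c_ in x$children[[q]]) rec(c_, depth + 1L)
  }
  rec(x$root, 0L)
  invisible(x)
}

tree_node_count <- function(tree) length(tree$labels)

# postorder traversal and leftmost-leaf index, for Zhang-Shasha
tree_postorder <- function(tree) {
  order <- integer(0)
  leftmost <- integer(0)
  rec <- function(q) {
    kids <- tree$children[[q]]
    first_leaf <- NA_integer_
    for (c_ in kids) {
      lf <- rec(c_)
      if (is.na(first_leaf)) first_leaf <- lf
    }
    order <<- c(order, q)
    idx <- length(order)
    lf <- if (is.na(first_leaf)) idx else first_leaf
    leftmost[idx] <<- lf
    lf
  }
  rec(tree$root)
  list(labels = tree$labels[order], leftmost = leftmost)
}

#' Normalized structure-similarity score
#'
#' Ordered tree-edit distance (Zhang-Shasha) between the element trees of
#' two structures with unit-cost relabel/insert/delete, normalized as
#' `1 - d / max(|a|, |b|)` and clamped to `[0, 1]`. Identical trees score 1;
#' the score is symmetric.
#'
#' @param a,b `structure_tree` objects (see [to_tree()]).
#' @return similarity in `[0, 1]`.
#' @export
similarity_score <- function(a, b) {
  d <- tree_edit_distance(a, b)
  max(0, 1 - d / max(tree_node_count(a), tree_node_count(b)))
}

#' Ordered tree-edit distance (Zhang-Shasha)
#'
#' @param a,b `structure_tree` objects.
#' @param cost_relabel cost of replacing one label with a different one.
#' @return the edit distance (numeric).
#' @export
tree_edit_distance <- function(a, b, cost_relabel = 1) {
  ta <- tree_postorder(a); tb <- tree_postorder(b)
  la <- ta$labels; lb <- tb$labels
  n1 <- length(la); n2 <- length(lb)
  l1 <- ta$leftmost; l2 <- tb$leftmost
  kr1 <- sort(which(!duplicated(l1, fromLast = TRUE)))
  kr2 <- sort(which(!duplicated(l2, fromLast = TRUE)))
  td <- matrix(0, n1, n2)
  gamma <- function(x, y) if (identical(x, y)) 0 else cost_relabel
  for (i1 in kr1) for (j1 in kr2) {
    li <- l1[i1]; lj <- l2[j1]
    m <- i1 - li + 2L; nn <- j1 - lj + 2L
    fd <- matrix(0, m, nn)
    fd[, 1] <- 0:(m - 1L)
    fd[1, ] <- 0:(nn - 1L)
    for (x in 2:m) for (y in 2:nn) {
      ix <- li + x - 2L; jy <- lj + y - 2L
      if (l1[ix] == li && l2[jy] == lj) {
        fd[x, y] <- min(fd[x - 1L, y] + 1,
                        fd[x, y - 1L] + 1,
                        fd[x - 1L, y - 1L] + gamma(la[ix], lb[jy]))
        td[ix, jy] <- fd[x, y]
      } else {
        fd[x, y] <- min(fd[x - 1L, y] + 1,
                        fd[x, y - 1L] + 1,
                        fd[l1[ix] - li + 1L, l2[jy] - lj + 1L] + td[ix, jy])
      }
    }
  }
  td[n1, n2]
}

#' Total stem length
#'
#' Sum of stem lengths (in base pairs) over all stems of a structure.
#'
#' @param elements output of [annotate_elements()].
#' @return total paired length in bp (0 for a fully unpaired structure).
#' @export
stem_length_summary <- function(elements) {
  sum(vapply(elements, function(e)
    if (e$kind == "stem") e$dims else 0L, numeric(1)))
}
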