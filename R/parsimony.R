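# Maximum-parsimony sample tree from binary mutation presence/absence.
# Small cohorts only (3-8 samples): exhaustive search over unrooted binary
# topologies, per-character Fitch counts, branch lengths from a Fitch
# backtrace that prefers the ancestral (absent) state at ties, reporting
# rooted at the matched normal.
#
# Internal tree encoding: edge matrix over node ids, tips 1..n (tip 1 is the
# normal), internal nodes n+1 .. 2n-2, as in ape's unrooted "phylo" edges.

#' Build a binary mutation presence matrix
#'
#' Rows are samples (the matched normal first, as an all-absent outgroup),
#' columns are mutations; entry 1 means the mutation was called in that
#' sample. Characters can be restricted to nonsynonymous mutations, the
#' usual choice when branch lengths are to count protein-changing events.
#'
#' @param calls named list of called variant-key vectors, one element per
#'   non-normal sample (e.g. `apply_filters(...)$calls`). At least two
#'   non-normal samples are required.
#' @param table the [variant_table()] the calls were made from.
#' @param nonsynonymous_only drop characters not annotated nonsynonymous.
#' @return An object of class `mutation_matrix`: list with `samples`,
#'   binary `mat` (samples x characters) and the `nonsynonymous_only` flag.
#' @export
build_mutation_matrix <- function(calls, table, nonsynonymous_only = FALSE) {
  validate_variant_table(table)
  if (length(calls) < 2L)
    stop("build_mutation_matrix: need calls for at least 2 non-normal samples",
         call. = FALSE)
  roles <- sample_roles(table)
  if (any(!names(calls) %in% names(roles)[roles != "normal"]))
    stop("build_mutation_matrix: calls must be keyed by non-normal sample ids",
         call. = FALSE)
  keys <- variant_keys(table)
  bad <- setdiff(unique(unlist(calls)), keys)
  if (length(bad))
    stop("build_mutation_matrix: called variant(s) not in table: ",
         paste(bad, collapse = ", "), call. = FALSE)
  chars <- keys[keys %in% unlist(calls)]           # table order, de-duplicated
  if (nonsynonymous_only)
    chars <- chars[table$variants$nonsynonymous[match(chars, keys)]]
  if (!length(chars))
    stop("build_mutation_matrix: no characters left after filtering",
         call. = FALSE)
  samples <- c(.normal_id(table), names(calls))
  mat <- matrix(0L, nrow = length(samples), ncol = length(chars),
                dimnames = list(samples, chars))
  for (id in names(calls))
    mat[id, intersect(calls[[id]], chars)] <- 1L
  structure(list(samples = samples, mat = mat,
                 nonsynonymous_only = isTRUE(nonsynonymous_only)),
            class = "mutation_matrix")
}

#' @export
print.mutation_matrix <- function(x, ...) {
  cat(sprintf("mutation_matrix: %d sample(s) x %d character(s)%s\n",
              nrow(x$mat), ncol(x$mat),
              if (x$nonsynonymous_only) " (nonsynonymous only)" else ""))
  print(rowSums(x$mat))
  invisible(x)
}

# --- topology enumeration ---------------------------------------------------

# All unrooted binary topologies on n labelled tips (n >= 3), built by
# inserting tip k on every edge: 1, 3, 15, 105, ... trees.
.all_topologies <- function(n) {
  stopifnot(n >= 3L)
  trees <- list(matrix(c(n + 1L, 1L, n + 1L, 2L, n + 1L, 3L),
                       ncol = 2L, byrow = TRUE))
  if (n == 3L) return(trees)
  for (tip in 4:n) {
    v <- n + tip - 2L                      # id of the new internal node
    trees <- unlist(lapply(trees, function(e) {
      lapply(seq_len(nrow(e)), function(j) {
        rbind(e[-j, , drop = FALSE],
              c(e[j, 1L], v), c(v, e[j, 2L]), c(v, tip))
      })
    }), recursive = FALSE)
  }
  trees
}

# Orient an unrooted edge matrix from a root tip: parent pointers and a
# preorder (parents before children) starting at the root tip's neighbor.
.orient <- function(edges, root_tip) {
  n_nodes <- max(edges)
  adj <- vector("list", n_nodes)
  for (j in seq_len(nrow(edges))) {
    a <- edges[j, 1L]; b <- edges[j, 2L]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  top <- adj[[root_tip]][1L]
  parent <- integer(n_nodes)
  parent[top] <- root_tip
  stack <- top
  preorder <- integer(0)
  while (length(stack)) {
    node <- stack[length(stack)]
    stack <- stack[-length(stack)]
    preorder <- c(preorder, node)
    for (w in adj[[node]]) if (w != parent[node]) {
      parent[w] <- node
      stack <- c(stack, w)
    }
  }
  list(parent = parent, preorder = preorder, top = top, adj = adj)
}

# Fitch first pass over all characters at once. tip_states: matrix
# [n_tip x K] of 0/1. Returns per-character minimum change counts and the
# per-node candidate sets (bit 1 = absent, bit 2 = present) for backtrace.
.fitch_pass <- function(edges, n_tip, tip_states, root_tip = 1L) {
  K <- ncol(tip_states)
  ori <- .orient(edges, root_tip)
  n_nodes <- max(edges)
  sets <- matrix(0L, nrow = n_nodes, ncol = K)
  sets[seq_len(n_tip), ] <- tip_states + 1L      # 0 -> {absent}, 1 -> {present}
  counts <- integer(K)
  children <- split(ori$preorder[-1L], ori$parent[ori$preorder[-1L]])
  for (node in rev(ori$preorder)) {
    if (node <= n_tip) next
    ch <- children[[as.character(node)]]
    s <- sets[ch[1L], ]
    for (c2 in ch[-1L]) {
      inter <- bitwAnd(s, sets[c2, ])
      un <- bitwOr(s, sets[c2, ])
      ev <- inter == 0L
      counts <- counts + ev
      s <- ifelse(ev, un, inter)
    }
    sets[node, ] <- s
  }
  # virtual root on the normal pendant edge: combine root tip with its child
  inter <- bitwAnd(sets[root_tip, ], sets[ori$top, ])
  ev <- inter == 0L
  counts <- counts + ev
  list(counts = counts, sets = sets, orient = ori)
}

# Backtrace: assign 0/1 states top-down (root tip keeps its observed state;
# ties resolved toward absence) and count changes per oriented edge.
.fitch_backtrace <- function(pass, n_tip, tip_states, root_tip = 1L) {
  ori <- pass$orient
  K <- ncol(tip_states)
  n_nodes <- nrow(pass$sets)
  state <- matrix(NA_integer_, nrow = n_nodes, ncol = K)
  state[root_tip, ] <- tip_states[root_tip, ]
  for (node in ori$preorder) {
    p <- ori$parent[node]
    pstate <- state[p, ]
    sset <- pass$sets[node, ]
    keep <- bitwAnd(sset, pstate + 1L) > 0L
    state[node, ] <- ifelse(keep, pstate,
                            ifelse(bitwAnd(sset, 1L) > 0L, 0L, 1L))
  }
  nodes <- ori$preorder
  lens <- vapply(nodes, function(node)
    sum(state[node, ] != state[ori$parent[node], ]), integer(1))
  list(state = state,
       edges = data.frame(parent = ori$parent[nodes], child = nodes,
                          length = lens))
}

# --- public operations -------------------------------------------------------

#' Fitch parsimony length of a mutation matrix on a fixed topology
#'
#' Sums, over characters, the minimum number of presence/absence changes on
#' the given topology (Fitch's small-parsimony pass).
#'
#' @param matrix a [build_mutation_matrix()] result.
#' @param tree a `sample_tree` (from [best_tree()]) or an `ape` `"phylo"`
#'   object whose tip labels are the matrix samples.
#' @return Integer total parsimony length.
#' @export
fitch_length <- function(matrix, tree) {
  stopifnot(inherits(matrix, "mutation_matrix"))
  if (inherits(tree, "sample_tree")) {
    edges <- tree$.edges
    tips <- tree$.tip_labels
  } else if (inherits(tree, "phylo")) {
    if (!requireNamespace("ape", quietly = TRUE))
      stop("fitch_length: package 'ape' is required for phylo input",
           call. = FALSE)
    un <- ape::unroot(tree)
    edges <- un$edge
    tips <- un$tip.label
  } else stop("fitch_length: unsupported tree representation", call. = FALSE)
  if (!setequal(tips, matrix$samples))
    stop("fitch_length: tree tips and matrix samples differ", call. = FALSE)
  tip_states <- matrix$mat[tips, , drop = FALSE]
  sum(.fitch_pass(edges, length(tips), tip_states)$counts)
}

# canonical newick: children ordered by the sorted label set of their clade
.canon_newick <- function(edges, tip_labels, root_tip = 1L,
                          branch = NULL) {
  ori <- .orient(edges, root_tip)
  children <- split(ori$preorder[-1L], ori$parent[ori$preorder[-1L]])
  elen <- if (is.null(branch)) NULL else
    setNames(branch$length, paste(branch$parent, branch$child))
  fmt_len <- function(p, c)
    if (is.null(elen)) "" else sprintf(":%d", elen[[paste(p, c)]])
  rec <- function(node) {
    if (node <= length(tip_labels))
      return(list(str = tip_labels[node], key = tip_labels[node]))
    subs <- lapply(children[[as.character(node)]], function(ch) {
      r <- rec(ch)
      r$str <- paste0(r$str, fmt_len(node, ch))
      r
    })
    subs <- subs[order(vapply(subs, `[[`, "", "key"))]
    list(str = paste0("(", paste(vapply(subs, `[[`, "", "str"),
                                 collapse = ","), ")"),
         key = paste(sort(unlist(strsplit(
           vapply(subs, `[[`, "", "key"), ","))), collapse = ","))
  }
  top <- rec(ori$top)
  root_lab <- tip_labels[root_tip]
  paste0("(", root_lab,
         if (is.null(elen)) "" else ":0", ",",
         top$str,
         if (is.null(elen)) "" else
           sprintf(":%d", elen[[paste(root_tip, ori$top)]]),
         ");")
}

#' Maximum-parsimony tree of the cohort samples
#'
#' Exhaustively scores every unrooted binary topology over the samples
#' (feasible for the 3-8 samples these cohorts have) by total Fitch
#' parsimony length and returns a minimum-length tree, reported rooted at
#' the matched normal. Branch lengths count the mutations assigned to each
#' branch by a Fitch backtrace that prefers the ancestral (absent) state at
#' ties, so gains are pushed toward the leaves. Ties between topologies are
#' broken by the lexicographic order of their canonical newick strings.
#'
#' @param matrix a [build_mutation_matrix()] result with 3-8 samples
#'   (including the normal).
#' @return An object of class `sample_tree`: list with `newick` (integer
#'   branch lengths), `total_length`, `branch_lengths` (edge table with
#'   clade labels) and `samples`.
#' @examples
#' coh <- simulate_cohort(preset_scenario("patient2"))
#' calls <- apply_filters(coh$table)
#' mm <- build_mutation_matrix(calls$calls, coh$table, nonsynonymous_only = TRUE)
#' best_tree(mm)
#' @export
best_tree <- function(matrix) {
  stopifnot(inherits(matrix, "mutation_matrix"))
  samples <- matrix$samples
  n <- length(samples)
  if (n < 3L)
    stop("best_tree: need at least 3 samples (including the normal)",
         call. = FALSE)
  if (n > 8L)
    stop("best_tree: exhaustive search supports at most 8 samples; use ",
         "dedicated phylogenetics software (e.g. phangorn) for larger cohorts",
         call. = FALSE)
  # deterministic tip order: normal first, remaining samples sorted
  tips <- c(samples[1L], sort(samples[-1L]))
  tip_states <- matrix$mat[tips, , drop = FALSE]
  topos <- .all_topologies(n)
  passes <- lapply(topos, .fitch_pass, n_tip = n, tip_states = tip_states)
  totals <- vapply(passes, function(p) sum(p$counts), integer(1))
  best_i <- which(totals == min(totals))
  if (length(best_i) > 1L) {
    nwk <- vapply(best_i, function(i) .canon_newick(topos[[i]], tips),
                  character(1))
    best_i <- best_i[order(nwk)]
  }
  i <- best_i[1L]
  bt <- .fitch_backtrace(passes[[i]], n, tip_states)
  total <- sum(passes[[i]]$counts)
  stopifnot(sum(bt$edges$length) == total)   # backtrace attains the minimum
  clade_label <- local({
    ori <- passes[[i]]$orient
    lab <- character(max(topos[[i]]))
    lab[seq_len(n)] <- tips
    for (node in rev(ori$preorder)) if (node > n) {
      ch <- ori$preorder[ori$parent[ori$preorder] == node]
      lab[node] <- paste0("{", paste(sort(unlist(strsplit(
        gsub("[{}]", "", lab[ch]), "\\+"))), collapse = "+"), "}")
    }
    lab
  })
  branch <- bt$edges
  branch$parent_label <- clade_label[branch$parent]
  branch$child_label <- clade_label[branch$child]
  structure(list(
    newick = .canon_newick(topos[[i]], tips, branch = bt$edges),
    total_length = as.integer(total),
    branch_lengths = branch[, c("parent_label", "child_label", "length")],
    samples = tips,
    .edges = topos[[i]], .tip_labels = tips),
    class = "sample_tree")
}

#' Serialize a sample tree to newick
#'
#' Branch lengths are integers (mutation counts); child order is canonical
#' (lexicographic by clade leaf set), so the string is invariant under
#' permutation of the input sample order.
#'
#' @param tree a `sample_tree` from [best_tree()].
#' @return Newick string, rooted at the normal.
#' @export
to_newick <- function(tree) {
  stopifnot(inherits(tree, "sample_tree"))
  tree$newick
}

#' @export
print.sample_tree <- function(x, ...) {
  cat("sample_tree (maximum parsimony, rooted at normal)\n")
  cat("  ", x$newick, "\n", sep = "")
  cat("  total length:", x$total_length, "mutations\n")
  invisible(x)
}
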