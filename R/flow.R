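# Edmonds-Karp maximum flow and the Picard-Queyranne closure structure of all
# minimum cuts. Undirected unit edges become a pair of mutually-reverse arcs
# of capacity 1; super-terminals absorb multiple sources/sinks through
# infinite-capacity arcs.

# Solve A x = b over GF(2). A: r x c 0/1 matrix, b: length-r 0/1 vector.
# Returns a particular solution (free variables set to 0) or NULL when the
# system is inconsistent.
gf2_solve <- function(A, b) {
  A <- (A %% 2L); b <- (b %% 2L)
  r <- nrow(A); c <- ncol(A)
  if (is.null(r) || r == 0L) return(integer(c))
  M <- cbind(A, b)
  piv_col <- integer(0)
  row <- 1L
  for (col in seq_len(c)) {
    if (row > r) break
    p <- which(M[row:r, col] == 1L)
    if (!length(p)) next
    p <- p[1L] + row - 1L
    if (p != row) M[c(p, row), ] <- M[c(row, p), ]
    hits <- which(M[, col] == 1L)
    hits <- hits[hits != row]
    if (length(hits)) {
      M[hits, ] <- (M[hits, , drop = FALSE] +
                      matrix(M[row, ], nrow = length(hits), ncol = c + 1L,
                             byrow = TRUE)) %% 2L
    }
    piv_col[row] <- col
    row <- row + 1L
  }
  # consistency: zero rows must have zero rhs
  if (row <= r && any(M[row:r, c + 1L] == 1L)) return(NULL)
  x <- integer(c)
  for (rr in seq_len(row - 1L)) x[piv_col[rr]] <- M[rr, c + 1L]
  x
}

#' Build a unit-capacity flow network between two vertex sets
#'
#' Each undirected edge becomes two oppositely directed arcs of capacity 1
#' that serve as each other's residual reverse; a super source feeds every
#' vertex of `sources` and every vertex of `sinks` feeds a super sink through
#' infinite-capacity arcs.
#'
#' @param edges data.frame with columns `v1`, `v2`; row names/positions are
#'   the undirected edge ids reported in cuts.
#' @param sources,sinks disjoint vertex id vectors.
#' @param edge_ids optional ids to report for each row of `edges`.
#' @return object of class `flow_network`: node table, arc table (`from`,
#'   `to`, `cap`, `flow`, `rev`, `edge_id`), adjacency list, `s`, `t`.
#' @export
make_flow_network <- function(edges, sources, sinks,
                              edge_ids = seq_len(nrow(edges))) {
  node_ids <- unique(c(edges$v1, edges$v2, sources, sinks))
  p <- length(node_ids)
  s <- p + 1L; t <- p + 2L
  nix <- function(v) match(v, node_ids)
  from <- integer(0); to <- integer(0); cap <- numeric(0)
  rev <- integer(0); eid <- integer(0)
  add_pair <- function(a, b, c_ab, c_ba, id) {
    k <- length(from)
    from[k + 1L] <<- a; to[k + 1L] <<- b; cap[k + 1L] <<- c_ab
    from[k + 2L] <<- b; to[k + 2L] <<- a; cap[k + 2L] <<- c_ba
    rev[k + 1L] <<- k + 2L; rev[k + 2L] <<- k + 1L
    eid[k + 1L] <<- id; eid[k + 2L] <<- id
  }
  for (r in seq_len(nrow(edges))) {
    add_pair(nix(edges$v1[r]), nix(edges$v2[r]), 1, 1, edge_ids[r])
  }
  for (v in sources) add_pair(s, nix(v), Inf, 0, NA_integer_)
  for (v in sinks) add_pair(nix(v), t, Inf, 0, NA_integer_)
  n_nodes <- p + 2L
  adj <- vector("list", n_nodes)
  for (a in seq_along(from)) adj[[from[a]]] <- c(adj[[from[a]]], a)
  structure(list(n_nodes = n_nodes, s = s, t = t, node_ids = node_ids,
                 arcs = data.frame(from = from, to = to, cap = cap,
                                   flow = 0, rev = rev, edge_id = eid),
                 adj = adj), class = "flow_network")
}

#' Edmonds-Karp maximum flow with an abort bound
#'
#' Shortest augmenting paths by BFS; returns `NULL` as soon as the flow value
#' exceeds `bound` (the caller then skips this partition), otherwise the
#' maximum flow value (equal to the minimum cut value) and the network with
#' final flows, from which the residual graph is read.
#'
#' @param net a [make_flow_network()] object.
#' @param bound nonnegative integer.
#' @return list with `value` and `net`, or `NULL` when the bound is exceeded.
#' @export
max_flow_min_cut <- function(net, bound) {
  arcs <- net$arcs
  value <- 0
  repeat {
    # BFS on the residual graph
    parent_arc <- rep(NA_integer_, net$n_nodes)
    seen <- rep(FALSE, net$n_nodes)
    seen[net$s] <- TRUE
    queue <- c(net$s)
    while (length(queue) && !seen[net$t]) {
      u <- queue[1L]; queue <- queue[-1L]
      for (a in net$adj[[u]]) {
        v <- arcs$to[a]
        if (!seen[v] && arcs$cap[a] - arcs$flow[a] > 0) {
          seen[v] <- TRUE
          parent_arc[v] <- a
          if (v == net$t) break
          queue <- c(queue, v)
        }
      }
    }
    if (!seen[net$t]) break
    # bottleneck along the path
    path <- integer(0)
    v <- net$t
    aug <- Inf
    while (v != net$s) {
      a <- parent_arc[v]
      path <- c(path, a)
      aug <- min(aug, arcs$cap[a] - arcs$flow[a])
      v <- arcs$from[a]
    }
    for (a in path) {
      arcs$flow[a] <- arcs$flow[a] + aug
      arcs$flow[arcs$rev[a]] <- arcs$flow[arcs$rev[a]] - aug
    }
    value <- value + aug
    if (value > bound) return(NULL)
  }
  net$arcs <- arcs
  list(value = value, net = net)
}

#' Condense the residual graph into the closure DAG of all mincuts
#'
#' The residual relation R has an arc (i, j) when arc (i, j) has slack or the
#' opposite arc carries flow. The source sides of minimum cuts are exactly the
#' successor-closed component sets containing the source component and not the
#' sink's: the source's component and its successors are forced in, the
#' sink's component and its predecessors are forced out, and every
#' successor-closed choice over the remaining ("free") components induces a
#' distinct minimum cut.
#'
#' @param net a `flow_network` with final flows (from [max_flow_min_cut()]).
#' @return object of class `closure_dag`: `comp_of` (node -> component),
#'   `n_comp`, `succ` (component adjacency list), `forced_source`,
#'   `forced_sink`, `free` (topologically sorted), plus the network.
#' @export
build_closure_dag <- function(net) {
  arcs <- net$arcs
  res <- arcs$cap - arcs$flow > 0
  rfrom <- arcs$from[res]; rto <- arcs$to[res]
  g <- igraph::graph_from_edgelist(cbind(rfrom, rto), directed = TRUE)
  g <- igraph::add_vertices(g, max(net$n_nodes - igraph::vcount(g), 0L))
  comp_of <- igraph::components(g, mode = "strong")$membership
  n_comp <- max(comp_of)
  succ <- vector("list", n_comp)
  for (a in which(res)) {
    ca <- comp_of[arcs$from[a]]; cb <- comp_of[arcs$to[a]]
    if (ca != cb) succ[[ca]] <- union(succ[[ca]], cb)
  }
  reach <- function(start, adj) {
    seen <- rep(FALSE, n_comp)
    stack <- start
    while (length(stack)) {
      c0 <- stack[length(stack)]; stack <- stack[-length(stack)]
      if (seen[c0]) next
      seen[c0] <- TRUE
      stack <- c(stack, adj[[c0]])
    }
    which(seen)
  }
  pred <- vector("list", n_comp)
  for (c0 in seq_len(n_comp)) for (c1 in succ[[c0]]) {
    pred[[c1]] <- c(pred[[c1]], c0)
  }
  forced_source <- reach(comp_of[net$s], succ)
  forced_sink <- reach(comp_of[net$t], pred)
  if (length(intersect(forced_source, forced_sink))) {
    ped_error("flow_internal",
              "source and sink closures intersect: flow was not maximum")
  }
  free <- setdiff(seq_len(n_comp), c(forced_source, forced_sink))
  # topological order of the free components (edges point to successors)
  topo <- integer(0)
  temp <- rep(0L, n_comp)
  visit <- function(c0) {
    if (temp[c0] != 0L) return(invisible())
    temp[c0] <<- 1L
    for (c1 in succ[[c0]]) if (c1 %in% free) visit(c1)
    topo[length(topo) + 1L] <<- c0
  }
  for (c0 in free) visit(c0)
  free_topo <- rev(topo[topo %in% free])    # predecessors first
  structure(list(comp_of = comp_of, n_comp = n_comp, succ = succ,
                 forced_source = forced_source, forced_sink = forced_sink,
                 free = free_topo, net = net), class = "closure_dag")
}

# undirected edge ids crossing the cut whose source side is the node set
# with components in S
cut_edges_for_closure <- function(dag, S_comps) {
  net <- dag$net
  arcs <- net$arcs
  inS <- dag$comp_of %in% S_comps
  cross <- inS[arcs$from] & !inS[arcs$to] & arcs$cap > 0
  sort(unique(arcs$edge_id[cross & !is.na(arcs$edge_id)]))
}

# enumerate every successor-closed choice over the free components, calling
# check(cut_edge_ids, S_comps); returns the first non-NULL result. `counter`
# is an environment collecting diagnostics (nodes expanded, cuts checked).
closure_search <- function(dag, check, counter = NULL) {
  free <- dag$free
  nf <- length(free)
  # decide components in reverse topological order so successors are known
  order_rev <- rev(free)
  chosen <- logical(nf)
  names(chosen) <- as.character(order_rev)
  succ_free <- lapply(order_rev, function(c0) {
    as.character(intersect(dag$succ[[c0]], free))
  })
  try_leaf <- function() {
    S <- c(dag$forced_source, as.integer(names(chosen)[chosen]))
    if (!is.null(counter)) counter$cuts <- counter$cuts + 1L
    check(cut_edges_for_closure(dag, S), S)
  }
  recurse <- function(pos) {
    if (!is.null(counter)) counter$nodes <- counter$nodes + 1L
    if (pos > nf) return(try_leaf())
    key <- as.character(order_rev[pos])
    # exclude
    chosen[key] <<- FALSE
    r <- recurse(pos + 1L)
    if (!is.null(r)) return(r)
    # include, only when all free successors are included
    if (all(chosen[succ_free[[pos]]])) {
      chosen[key] <<- TRUE
      r <- recurse(pos + 1L)
      chosen[key] <<- FALSE
      if (!is.null(r)) return(r)
    }
    NULL
  }
  recurse(1L)
}

#' Enumerate the minimum cuts generated by the closure DAG
#'
#' Every successor-closed choice over the free components yields a minimum
#' cut; this returns them all (for cross-checking against exhaustive
#' enumeration).
#'
#' @param dag a [build_closure_dag()] object.
#' @param max_cuts guard on the number of generated cuts.
#' @return list of cuts, each a list with `S` (source-side node indices) and
#'   `edges` (sorted undirected edge ids).
#' @export
closure_all_mincuts <- function(dag, max_cuts = 65536L) {
  out <- list()
  closure_search(dag, function(cut, S_comps) {
    nodes <- which(dag$comp_of %in% S_comps)
    out[[length(out) + 1L]] <<- list(S = sort(nodes), edges = cut)
    if (length(out) >= max_cuts) {
      ped_error("oracle_limits_exceeded", "too many mincuts to enumerate")
    }
    NULL
  })
  out
}
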