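# Graph Bipartization by Edge Removal with parity constraints, solved by
# iterative compression: edges are added one at a time in a deterministic
# order while a minimum-size parity-feasible removal set X is maintained;
# when X stops working, X' = X + the new edge is compressed back to size |X|
# by enumerating the 2^|X| valid partitions of V(X') and searching the
# minimum cuts between the partition sides (via the closure DAG) for a
# parity-feasible one.

#' Construct a bare GBER instance
#'
#' For tests and standalone use of [solve_gber()] on arbitrary multigraphs;
#' [pedigree_gber_instance()] builds the pedigree-derived form.
#'
#' @param edges data.frame with columns `v1`, `v2` (integer vertex ids);
#'   parallel edges allowed.
#' @param budget maximum number of removable edges.
#' @param parity_sets list of lists with `vids` and `offset` (see
#'   [brute_force_bipartization()]); side of the red anchor (or side "A" when
#'   there are no anchors) counts as red.
#' @param anchors optional named pair `c(red = , green = )` of vertex ids that
#'   must end on opposite sides.
#' @return object of class `gber_instance`.
#' @export
gber_instance <- function(edges, budget, parity_sets = list(),
                          anchors = NULL) {
  edges <- data.frame(v1 = as.integer(edges$v1), v2 = as.integer(edges$v2),
                      origin_eid = seq_len(nrow(edges)), role = "orig",
                      stringsAsFactors = FALSE)
  vids <- sort(unique(c(edges$v1, edges$v2,
                        unlist(lapply(parity_sets, `[[`, "vids")), anchors)))
  structure(list(edges = edges,
                 vertices = data.frame(tvid = vids, kind = "orig",
                                       color = "grey", member = NA_character_,
                                       orig_vid = vids,
                                       stringsAsFactors = FALSE),
                 budget = as.integer(budget), anchors = anchors,
                 parity_sets = parity_sets, baseline_cost = 0L,
                 baseline_eids = integer(0), orig = NULL),
            class = "gber_instance")
}

# Proper 2-coloring of the active edges plus parity feasibility.
#
# After removal the graph is bipartite; each connected component is colored
# up to a flip, anchor components are oriented by their anchor, and the
# remaining flips together with the colors of free vertices (parity-set
# members with no active edge) form a GF(2) system, one equation per parity
# set. Returns NULL when non-bipartite or the system is inconsistent,
# otherwise a witness: named vector over vertices ("red"/"green") covering
# present and free vertices.
two_color_witness <- function(active_edges, parity_sets, anchors) {
  present <- unique(c(active_edges$v1, active_edges$v2))
  np <- length(present)
  idx <- function(v) match(v, present)
  adj <- vector("list", np)
  for (r in seq_len(nrow(active_edges))) {
    a <- idx(active_edges$v1[r]); b <- idx(active_edges$v2[r])
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  part <- rep(NA_integer_, np)
  comp <- rep(NA_integer_, np)
  n_comp <- 0L
  for (v0 in seq_len(np)) {
    if (!is.na(comp[v0])) next
    n_comp <- n_comp + 1L
    comp[v0] <- n_comp; part[v0] <- 0L
    queue <- v0
    while (length(queue)) {
      u <- queue[1L]; queue <- queue[-1L]
      for (w in adj[[u]]) {
        if (is.na(comp[w])) {
          comp[w] <- n_comp
          part[w] <- 1L - part[u]
          queue <- c(queue, w)
        } else if (part[w] == part[u]) {
          return(NULL)                        # odd cycle
        }
      }
    }
  }
  # red(v) = part(v) XOR flip(comp(v)); fix anchor components
  flip_fixed <- rep(NA_integer_, n_comp)
  if (!is.null(anchors)) {
    ra <- idx(anchors[["red"]]); ga <- idx(anchors[["green"]])
    if (!is.na(ra)) flip_fixed[comp[ra]] <- 1L - part[ra]   # make red = 1
    if (!is.na(ga)) {
      want <- part[ga]                                       # make red = 0
      if (!is.na(flip_fixed[comp[ga]])) {
        if (flip_fixed[comp[ga]] != want) return(NULL)
      } else {
        flip_fixed[comp[ga]] <- want
      }
    }
  }
  free_comps <- which(is.na(flip_fixed))
  # free vertices: parity-set members with no active edge
  pvids <- unique(unlist(lapply(parity_sets, `[[`, "vids")))
  free_verts <- setdiff(pvids, present)
  unknowns <- c(paste0("f", free_comps), paste0("x", free_verts))
  A <- matrix(0L, nrow = length(parity_sets), ncol = length(unknowns))
  colnames(A) <- unknowns
  b <- integer(length(parity_sets))
  for (s in seq_along(parity_sets)) {
    ps <- parity_sets[[s]]
    rhs <- ps$offset
    for (v in ps$vids) {
      iv <- idx(v)
      if (is.na(iv)) {
        A[s, paste0("x", v)] <- (A[s, paste0("x", v)] + 1L) %% 2L
      } else {
        rhs <- rhs + part[iv]
        cid <- comp[iv]
        if (!is.na(flip_fixed[cid])) {
          rhs <- rhs + flip_fixed[cid]
        } else {
          key <- paste0("f", cid)
          A[s, key] <- (A[s, key] + 1L) %% 2L
        }
      }
    }
    b[s] <- rhs %% 2L
  }
  sol <- gf2_solve(A, b)
  if (is.null(sol)) return(NULL)
  names(sol) <- unknowns
  flip <- flip_fixed
  if (length(free_comps)) flip[free_comps] <- sol[paste0("f", free_comps)]
  if (is.null(anchors) && n_comp > 0L) flip[is.na(flip)] <- 0L
  red <- integer(0)
  if (np) red <- (part + flip[comp]) %% 2L
  out <- stats::setNames(ifelse(red == 1L, "red", "green"), present)
  if (length(free_verts)) {
    out[as.character(free_verts)] <-
      ifelse(sol[paste0("x", free_verts)] == 1L, "red", "green")
  }
  out
}

# is `removed` (row indices) a parity-feasible bipartization set for the
# first `i` edges? returns the witness coloring or NULL
gber_check <- function(inst, i, removed) {
  active <- setdiff(seq_len(i), removed)
  two_color_witness(inst$edges[active, , drop = FALSE], inst$parity_sets,
                    inst$anchors)
}

# Compression: from a removal set X' of size k'+1 for the first i edges, find
# a parity-feasible set of size <= k', or NULL. Implements the disjointness
# subdivision, the 2^k' valid partitions, bounded max-flow, and the
# parity-directed closure search; `counter` collects diagnostics.
gber_compress <- function(inst, i, X_prime, mode, counter) {
  k_p <- length(X_prime) - 1L
  edges_i <- inst$edges[seq_len(i), , drop = FALSE]
  all_v <- unique(c(edges_i$v1, edges_i$v2))
  base_id <- max(all_v) + 1L
  # subdivide each X' edge y-z into y-a, (a-b), b-z; middle edge a-b is the
  # new X' and is absent from the cut graph H
  h_v1 <- integer(0); h_v2 <- integer(0); h_map <- integer(0)
  sub_pairs <- matrix(0L, nrow = length(X_prime), ncol = 2L)
  in_X <- seq_len(i) %in% X_prime
  for (r in seq_len(i)) {
    if (!in_X[r]) {
      h_v1 <- c(h_v1, edges_i$v1[r]); h_v2 <- c(h_v2, edges_i$v2[r])
      h_map <- c(h_map, r)
    }
  }
  for (xi in seq_along(X_prime)) {
    r <- X_prime[xi]
    a <- base_id; b <- base_id + 1L; base_id <- base_id + 2L
    sub_pairs[xi, ] <- c(a, b)
    h_v1 <- c(h_v1, edges_i$v1[r], b); h_v2 <- c(h_v2, a, edges_i$v2[r])
    h_map <- c(h_map, r, r)
  }
  H <- data.frame(v1 = h_v1, v2 = h_v2)
  n_x <- length(X_prime)
  # 2^(n_x - 1) valid partitions: first middle edge's orientation fixed
  for (code in 0:(2^(max(n_x - 1L, 0L)) - 1L)) {
    counter$phi <- counter$phi + 1L
    orient <- c(0L, if (n_x > 1L) {
      as.integer(intToBits(code))[seq_len(n_x - 1L)]
    })
    A_phi <- ifelse(orient == 0L, sub_pairs[, 1L], sub_pairs[, 2L])
    B_phi <- ifelse(orient == 0L, sub_pairs[, 2L], sub_pairs[, 1L])
    net <- make_flow_network(H, A_phi, B_phi, edge_ids = seq_len(nrow(H)))
    counter$flows <- counter$flows + 1L
    mf <- max_flow_min_cut(net, bound = k_p)
    if (is.null(mf)) next                     # mincut exceeds k', skip phi
    dag <- build_closure_dag(mf$net)
    found <- closure_search(dag, function(cut_rows, S_comps) {
      removed <- sort(unique(h_map[cut_rows]))
      if (length(removed) > k_p) return(NULL)
      wit <- gber_check(inst, i, removed)
      if (is.null(wit)) return(NULL)
      list(removed = removed, witness = wit)
    }, counter = counter)
    if (!is.null(found)) return(found)
  }
  if (mode == "exhaustive_fallback" && k_p >= 0L) {
    cand_rows <- seq_len(i)
    if (choose(length(cand_rows), k_p) <= 2e5) {
      counter$fallback_used <- TRUE
      combos <- if (k_p == 0L) list(integer(0)) else {
        utils::combn(cand_rows, k_p, simplify = FALSE)
      }
      for (removed in combos) {
        wit <- gber_check(inst, i, removed)
        if (!is.null(wit)) return(list(removed = removed, witness = wit))
      }
    }
  }
  NULL
}

#' Solve GBER with parity constraints by iterative compression
#'
#' Maintains a minimum-size parity-feasible edge bipartization set while
#' inserting edges in a deterministic order (anchor gadget edges first, then
#' provenance order); whenever the set must grow it is first compressed via
#' the valid-partition / minimum-cut search. Infeasibility within the budget
#' is a result, not an error.
#'
#' @param inst a `gber_instance`.
#' @param mode `"paper_faithful"` searches parity feasibility among minimum
#'   cuts only; `"exhaustive_fallback"` additionally brute-forces removal
#'   subsets of the compression size when that search fails (guarding against
#'   the open question of whether a feasible non-minimum cut can be required).
#' @return object of class `gber_result`: `feasible`, `removed` (row indices
#'   into `inst$edges`), `coloring` (named "red"/"green" witness over present
#'   and parity-free vertices), `cost`, and `diagnostics` (per-iteration |X|,
#'   partitions tried, flows computed, closure nodes expanded, mode used).
#' @export
solve_gber <- function(inst, mode = c("paper_faithful",
                                      "exhaustive_fallback")) {
  mode <- match.arg(mode)
  stopifnot(inherits(inst, "gber_instance"))
  counter <- new.env(parent = emptyenv())
  counter$phi <- 0L; counter$flows <- 0L; counter$nodes <- 0L
  counter$cuts <- 0L; counter$fallback_used <- FALSE
  diag_x <- integer(0)
  result <- function(feasible, removed = integer(0), witness = NULL) {
    structure(list(
      feasible = feasible, removed = removed, coloring = witness,
      cost = length(removed),
      diagnostics = list(x_sizes = diag_x, phi_tried = counter$phi,
                         flows = counter$flows,
                         closure_nodes = counter$nodes,
                         cuts_checked = counter$cuts,
                         mode = mode,
                         fallback_used = counter$fallback_used)),
      class = "gber_result")
  }
  if (inst$budget < 0L) return(result(FALSE))
  M <- nrow(inst$edges)
  X <- integer(0)
  witness <- two_color_witness(inst$edges[0, , drop = FALSE],
                               inst$parity_sets, inst$anchors)
  if (is.null(witness)) return(result(FALSE))   # parity unsatisfiable outright
  for (i in seq_len(M)) {
    wit <- gber_check(inst, i, X)
    if (is.null(wit)) {
      X_prime <- c(X, i)
      comp <- gber_compress(inst, i, X_prime, mode, counter)
      if (is.null(comp)) {
        X <- X_prime
        wit <- gber_check(inst, i, X)
        if (is.null(wit)) {
          # X' itself is not feasible (parity cannot be met at all)
          diag_x <- c(diag_x, length(X))
          return(result(FALSE))
        }
      } else {
        X <- comp$removed
        wit <- comp$witness
      }
      if (length(X) > inst$budget) {
        diag_x <- c(diag_x, length(X))
        return(result(FALSE))
      }
    }
    witness <- wit
    diag_x <- c(diag_x, length(X))
  }
  result(TRUE, removed = X, witness = witness)
}

#' @export
print.gber_result <- function(x, ...) {
  cat(sprintf("<gber_result> %s, %d edges removed (phi tried: %d)\n",
              if (x$feasible) "feasible" else "infeasible", x$cost,
              x$diagnostics$phi_tried))
  invisible(x)
}

#' Parity-directed search over the closure DAG
#'
#' Backtracks over the free components in reverse topological order,
#' enumerating successor-closed unions with the forced source side; each
#' induced minimum cut is tested with the supplied predicate (typically
#' parity feasibility of the residual coloring) and the first success is
#' returned.
#'
#' @param dag a [build_closure_dag()] object.
#' @param check function(cut_edge_ids, S_comps) returning `NULL` to continue
#'   or any non-NULL value to stop.
#' @return the first non-NULL `check` value, or `NULL`.
#' @export
parity_feasible_closure <- function(dag, check) {
  closure_search(dag, check)
}
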