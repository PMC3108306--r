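# hand-built signed graphs for transformation tests
sg <- function(n, v1, v2, sign) {
  structure(list(n_vertices = as.integer(n),
                 edges = data.frame(v1 = v1, v2 = v2, sign = sign)),
            class = "signed_graph")
}

test_that("line index of a partition counts violated edge constraints", {
  g0 <- sg(3, integer(0), integer(0), integer(0))
  expect_equal(line_index_of_partition(
    g0, c("1" = "V1", "2" = "V2", "3" = "V1")), 0L)

  g1 <- sg(2, 1L, 2L, -1L)
  expect_equal(line_index_of_partition(g1, c("1" = "V1", "2" = "V1")), 1L)
  expect_equal(line_index_of_partition(g1, c("1" = "V1", "2" = "V2")), 0L)
  expect_error(line_index_of_partition(g1, c("1" = "V1")),
               class = "partial_partition")

  tri <- sg(3, c(1L, 2L, 1L), c(2L, 3L, 3L), c(1L, 1L, -1L))
  # exhaustive check over all 2^3 partitions gives minimum 1
  best <- Inf
  for (code in 0:7) {
    side <- ifelse(as.integer(intToBits(code))[1:3] == 1L, "V1", "V2")
    best <- min(best, line_index_of_partition(
      tri, stats::setNames(side, 1:3)))
  }
  expect_equal(best, 1)
  expect_equal(brute_force_line_index(tri), 1)
})

test_that("single edges have line index zero", {
  expect_equal(brute_force_line_index(sg(2, 1L, 2L, 1L)), 0)
  expect_equal(brute_force_line_index(sg(2, 1L, 2L, -1L)), 0)
})

test_that("positive-to-negative transform preserves the line index", {
  gneg <- sg(3, c(1L, 2L), c(2L, 3L), c(-1L, -1L))
  tg <- positive_to_negative(gneg)
  expect_equal(nrow(tg$edges), 2L)
  expect_true(all(tg$edges$role == "orig"))

  gpos <- sg(2, 1L, 2L, 1L)
  tgp <- positive_to_negative(gpos)
  expect_equal(nrow(tgp$edges), 2L)
  expect_true(all(tgp$edges$weight == -1L))
  expect_equal(sum(tgp$vertices$kind == "dum"), 1L)
  expect_equal(brute_force_line_index(tgp), 0)

  tri <- sg(3, c(1L, 2L, 1L), c(2L, 3L, 3L), c(1L, 1L, -1L))
  tri_t <- positive_to_negative(tri)
  expect_equal(nrow(tri_t$vertices), 5L)
  expect_equal(brute_force_line_index(tri_t), 1)
})

test_that("line index is invariant under the transform on random signed graphs", {
  for (s in 1:40) {
    g <- random_signed_graph(sample(3:8, 1), sample(2:12, 1),
                             p_positive = stats::runif(1), seed = s)
    expect_equal(brute_force_line_index(positive_to_negative(g)),
                 brute_force_line_index(g),
                 label = sprintf("seed %d", s))
  }
})

test_that("constant costs are folded out before merging", {
  # a fake pedigree-graph-shaped transform: two resolved vertices joined by a
  # negative edge, plus an unrelated grey vertex
  mk_tg <- function(c1, c2) {
    structure(list(
      vertices = data.frame(tvid = 1:3, kind = "orig",
                            color = c(c1, c2, "grey"),
                            member = c("a", "b", "c"), orig_vid = 1:3,
                            stringsAsFactors = FALSE),
      edges = data.frame(v1 = 1L, v2 = 2L, weight = -1L, origin_eid = 7L,
                         role = "orig", stringsAsFactors = FALSE),
      baseline_cost = 0L, baseline_eids = integer(0),
      budget = NA_integer_, anchors = NULL, parity_sets = list(),
      orig = NULL), class = "signed_transform")
  }
  f1 <- fold_constant_costs(mk_tg("red", "green"))
  expect_equal(nrow(f1$edges), 0L)
  expect_equal(f1$baseline_cost, 0L)

  f2 <- fold_constant_costs(mk_tg("red", "red"))
  expect_equal(nrow(f2$edges), 0L)
  expect_equal(f2$baseline_cost, 1L)
  expect_equal(f2$baseline_eids, 7L)

  f3 <- fold_constant_costs(mk_tg("red", "grey"))
  expect_equal(nrow(f3$edges), 1L)
})

test_that("merging attaches resolved vertices to anchors joined by k+1 edges", {
  tg <- structure(list(
    vertices = data.frame(tvid = 1:3, kind = "orig",
                          color = c("red", "red", "grey"),
                          member = c("a", "b", "c"), orig_vid = 1:3,
                          stringsAsFactors = FALSE),
    edges = data.frame(v1 = c(1L, 2L), v2 = c(3L, 3L), weight = -1L,
                       origin_eid = 1:2, role = "orig",
                       stringsAsFactors = FALSE),
    baseline_cost = 0L, baseline_eids = integer(0),
    budget = NA_integer_, anchors = NULL, parity_sets = list(),
    orig = NULL), class = "signed_transform")
  mg <- merge_resolved(tg, k = 2L)
  expect_equal(mg$budget, 2L)
  ra <- mg$anchors[["red"]]
  expect_equal(sum(mg$edges$role == "anchor"), 3L)        # budget + 1
  reattached <- mg$edges[mg$edges$role == "orig", ]
  expect_true(all(reattached$v1 == ra))                   # both edges kept
  expect_equal(nrow(reattached), 2L)
})

test_that("the GBER instance is all-positive bipartization with provenance", {
  pg <- build_pedigree_graph(canonical_family())
  inst <- pedigree_gber_instance(pg, 1L)
  expect_s3_class(inst, "gber_instance")
  expect_equal(inst$budget, 1L)
  # anchors first in the deterministic solver order
  expect_equal(inst$edges$role[1:2], c("anchor", "anchor"))
  # every non-synthetic edge maps to exactly one original signed edge
  orig <- inst$edges$origin_eid[inst$edges$role != "anchor"]
  expect_true(all(orig %in% pg$edges$eid))
  txt <- gber_to_text(inst)
  expect_match(txt[1], "budget 1")
})

test_that("anchor separation: in-budget solutions always split the anchors", {
  sim <- corpus_sim(23L)
  res <- solve_rhc(sim$pedigree, k_max = 4)
  expect_true(res$feasible)
  inst <- pedigree_gber_instance(res$graph, res$solver_k)
  sres <- solve_gber(inst)
  expect_true(sres$feasible)
  wit <- sres$coloring
  expect_equal(unname(wit[as.character(inst$anchors[["red"]])]), "red")
  expect_equal(unname(wit[as.character(inst$anchors[["green"]])]), "green")
})
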