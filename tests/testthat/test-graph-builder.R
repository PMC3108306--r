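test_that("member vertices follow the closest-pair coloring rules", {
  vt <- build_member_vertices(c(0, 1, 1, 2, 2))
  expect_equal(vt$i, c(1L, 2L, 4L))
  expect_equal(vt$j, c(2L, 3L, 5L))
  expect_equal(vt$color, c("red", "green", "grey"))
  expect_equal(vt$origin, c("primary_hom", "primary_hom", "primary_het"))

  vt0 <- build_member_vertices(c(0, 0, 0))
  expect_equal(vt0$color, c("green", "green"))

  expect_equal(nrow(build_member_vertices(c(2))), 0L)
})

test_that("the canonical family compiles to the expected constraints", {
  pg <- build_pedigree_graph(canonical_family())
  v <- pg$vertices
  # c2's primary vertex is transmission-forced green (mother homozygous at
  # both sites pins both deliveries)
  c2 <- v[v$member == "c2" & v$origin == "primary_het", ]
  expect_equal(c2$color, "green")
  expect_true(c2$forced)
  # c1 (het at site 1 only) yields a resolved constant partner for the father
  k1 <- v[v$member == "c1" & v$origin == "const", ]
  expect_equal(k1$color, "red")
  # the father's grey vertex carries one cost edge per child
  f12 <- v$vid[v$member == "f" & v$origin == "primary_het"]
  expect_equal(sum(pg$edges$v1 == f12), 2L)
  expect_setequal(pg$edges$trio, c("c1", "c2"))
  expect_true(all(pg$edges$pmember == "f"))
})

test_that("construction is deterministic and idempotent", {
  sim <- corpus_sim(3L)
  pg1 <- build_pedigree_graph(sim$pedigree)
  pg2 <- build_pedigree_graph(sim$pedigree)
  expect_identical(pg1$vertices, pg2$vertices)
  expect_identical(pg1$edges, pg2$edges)
  # re-running a trio pass adds nothing
  pg3 <- add_trio_edges(pg1, 1L)
  expect_identical(pg3$edges, pg1$edges)
  expect_identical(nrow(pg3$vertices), nrow(pg1$vertices))
})

test_that("a wide parental pair induces a supplementary vertex and its chain parity set", {
  # father and mother het only at the outer sites; the child het everywhere:
  # the parents' (1,5) pair is scored against the child's segment pattern,
  # which requires a supplementary child vertex chained over the primaries
  ped <- pedigree(id = c("f", "m", "c"), father = c(NA, NA, "f"),
                  mother = c(NA, NA, "m"),
                  geno = rbind(c(2, 0, 0, 0, 2),
                               c(2, 1, 1, 1, 2),
                               c(2, 2, 2, 2, 2)))
  pg <- build_pedigree_graph(ped)
  v <- pg$vertices
  supp <- v[v$member == "c" & v$origin == "supplementary", ]
  expect_equal(nrow(supp), 1L)
  expect_equal(c(supp$i, supp$j), c(1L, 5L))
  chain_sets <- Filter(function(ps) ps$kind == "chain", pg$parity_sets)
  expect_equal(length(chain_sets), 1L)
  expect_equal(length(chain_sets[[1]]$vids), 5L)  # anchor + 4 primaries
  expect_equal(chain_sets[[1]]$member, "c")
  # an odd number of red vertices violates the set, an even number satisfies
  chain_parity <- function(colors) {
    (chain_sets[[1]]$offset +
       sum(colors[as.character(chain_sets[[1]]$vids)] == "red")) %% 2L
  }
  odd <- stats::setNames(rep("green", nrow(v)), v$vid)
  odd[as.character(chain_sets[[1]]$vids)[1:3]] <- "red"
  expect_equal(chain_parity(odd), 1L)
  odd[as.character(chain_sets[[1]]$vids)[4]] <- "red"
  expect_equal(chain_parity(odd), 0L)
})

test_that("interacting transmissions are mediated by delivery vertices", {
  # child het at 1,2; both parents het at both sites: each parent's pair is
  # scored directly against the child's primary vertex (the all-free case)
  ped <- pedigree(id = c("f", "m", "c"), father = c(NA, NA, "f"),
                  mother = c(NA, NA, "m"),
                  geno = rbind(c(2, 2), c(2, 2), c(2, 2)))
  pg <- build_pedigree_graph(ped)
  cvid <- pg$vertices$vid[pg$vertices$member == "c" &
                            pg$vertices$origin == "primary_het"]
  expect_equal(sort(pg$edges$v2), c(cvid, cvid))
  expect_true(all(pg$edges$sign == 1L))
  # child het at one site / hom at the other: the two parents are coupled
  # through the shared delivery vertex by a +/- edge pair
  ped2 <- pedigree(id = c("f", "m", "c"), father = c(NA, NA, "f"),
                   mother = c(NA, NA, "m"),
                   geno = rbind(c(2, 2), c(2, 2), c(2, 0)))
  pg2 <- build_pedigree_graph(ped2)
  ev <- pg2$vertices$vid[pg2$vertices$origin == "delivery"]
  expect_length(ev, 1L)
  expect_setequal(pg2$edges$v2, ev)
  expect_setequal(pg2$edges$sign, c(1L, -1L))
})

test_that("size bounds hold with constant 3 on random pedigrees", {
  for (s in 1:200) {
    set.seed(s)
    spec <- simulation_spec(sample(1:3, 1), sample(1:3, 1), sample(2:3, 1),
                            m = sample(1:6, 1),
                            planted_recombinations = 0L, seed = s)
    sim <- simulate_pedigree(spec)
    n <- nrow(sim$pedigree$members)
    m <- ncol(sim$pedigree$geno)
    if (n > 10) next
    pg <- build_pedigree_graph(sim$pedigree)
    live <- sum(!pg$vertices$pruned)
    expect_lte(live, 3 * n * m^2)
    expect_lte(nrow(pg$edges), 3 * n * m^2)
    # structural sanity: no edge touches a pruned vertex, endpoints differ
    pruned <- pg$vertices$vid[pg$vertices$pruned]
    expect_false(any(pg$edges$v1 %in% pruned | pg$edges$v2 %in% pruned))
    expect_false(any(pg$edges$v1 == pg$edges$v2))
  }
})

test_that("forced colors and pruning passes are stable", {
  sim <- corpus_sim(17L)
  pg <- build_pedigree_graph(sim$pedigree)
  pg2 <- propagate_forced_colors(pg)
  expect_identical(pg2$vertices$color, pg$vertices$color)
  pg3 <- add_additional_vertices(pg)
  expect_identical(pg3$vertices$pruned, pg$vertices$pruned)
})

test_that("graph exports produce DOT and JSON views", {
  pg <- build_pedigree_graph(canonical_family())
  dot <- graph_to_dot(pg)
  expect_equal(dot[1], "graph pedigree {")
  expect_equal(dot[length(dot)], "}")
  expect_true(any(grepl("sign=1", dot)))
  tmp <- tempfile(fileext = ".json")
  graph_to_json(pg, tmp)
  parsed <- jsonlite::read_json(tmp)
  expect_named(parsed, c("vertices", "edges", "parity_sets", "log"))
  unlink(tmp)
})
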