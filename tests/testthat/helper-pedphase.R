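# Shared fixtures: all data is generated in code.

# father het/het, mother hom, children [2,0] and [2,2]: minimum is exactly one
# recombination event (the father cannot phase both children for free)
canonical_family <- function() {
  pedigree(id = c("f", "v", "c1", "c2"),
           father = c(NA, NA, "f", "f"), mother = c(NA, NA, "v", "v"),
           sex = c(1, 2, 1, 2),
           geno = rbind(c(2, 2), c(0, 0), c(2, 0), c(2, 2)))
}

# study-condition corpus: small families (1-2 couples, up to 3 generations),
# 2-4 SNP sites, 0-2 planted recombinations
corpus_sim <- function(seed) {
  set.seed(seed * 7L + 1L)
  tmpl <- sample(1:3, 1)
  spec <- if (tmpl == 1L) {
    simulation_spec(1, sample(1:3, 1), 2, m = sample(2:4, 1),
                    planted_recombinations = sample(0:2, 1), seed = seed)
  } else if (tmpl == 2L) {
    simulation_spec(2, 1, 2, m = sample(2:4, 1),
                    planted_recombinations = sample(0:2, 1), seed = seed)
  } else {
    simulation_spec(1, 2, 3, m = sample(2:4, 1),
                    planted_recombinations = sample(0:2, 1), seed = seed)
  }
  simulate_pedigree(spec)
}

# random unit-weight multigraph as a bare GBER instance edge list
random_multigraph <- function(n_vertices, n_edges, seed) {
  set.seed(seed)
  data.frame(v1 = sample.int(n_vertices, n_edges, replace = TRUE),
             v2 = sample.int(n_vertices, n_edges, replace = TRUE)) |>
    (\(d) {
      # no self-loops: resample collisions deterministically
      while (any(d$v1 == d$v2)) {
        idx <- d$v1 == d$v2
        d$v2[idx] <- (d$v2[idx] %% n_vertices) + 1L
      }
      d
    })()
}

# random small flow network: an undirected edge list plus terminal sets
random_flow_fixture <- function(seed) {
  set.seed(seed)
  n <- sample(4:8, 1)
  edges <- random_multigraph(n, sample(4:10, 1), seed + 1000L)
  make_flow_network(edges, sources = 1L, sinks = n)
}

expect_phases_consistent <- function(ped, phases) {
  for (u in ped$members$id) {
    expect_true(phase_consistent(phases[[u]], ped$geno[u, ]),
                label = sprintf("phase of %s consistent", u))
  }
}

# does a coloring satisfy every parity set of a pedigree graph?
parity_ok <- function(pg, colors) {
  for (ps in pg$parity_sets) {
    nred <- ps$offset + sum(colors[as.character(ps$vids)] == "red")
    if (nred %% 2L != 0L) return(FALSE)
  }
  TRUE
}
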