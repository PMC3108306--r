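test_that("compact and linkage dialects recode genotypes correctly", {
  lines <- c("F1 f 0 0 1 202",
             "F1 v 0 0 2 000",
             "F1 c f v 1 202")
  ped <- parse_pedigree(lines, dialect = "compact")
  expect_equal(unname(ped$geno["c", ]), c(2L, 0L, 2L))
  expect_equal(ped$members$father[ped$members$id == "c"], "f")
  expect_equal(ped$members$mother[ped$members$id == "c"], "v")

  lk <- c("F1 u 0 0 1 1 2  1 1  2 2")
  ped2 <- parse_pedigree(lk, dialect = "linkage")
  expect_equal(unname(ped2$geno["u", ]), c(2L, 0L, 1L))
})

test_that("malformed inputs raise distinct classed errors", {
  expect_error(parse_pedigree("F1 c f 1 202", dialect = "compact"),
               class = "ped_malformed_line")
  expect_error(parse_pedigree(c("F1 c 0 0 1 2x2"), dialect = "compact"),
               class = "ped_malformed_line")
  expect_error(parse_pedigree(c("F1 c 0 0 1 2?2"), dialect = "compact"),
               class = "ped_missing_data")
  expect_error(parse_pedigree(c("F1 u 0 0 1 1 0 1 1"), dialect = "linkage"),
               class = "ped_missing_data")
  expect_error(parse_pedigree(c("F1 a 0 0 1 22", "F1 b 0 0 2 222"),
                              dialect = "compact"),
               class = "ped_unequal_sites")
  expect_error(parse_pedigree(c("F1 a 0 0 1 22", "F1 c a x 1 22"),
                              dialect = "compact"),
               class = "ped_unknown_parent")
  # father present but mother absent violates the full-trio invariant
  expect_error(parse_pedigree(c("F1 f 0 0 1 22", "F1 c f 0 1 22"),
                              dialect = "compact"),
               class = "ped_half_trio")
})

test_that("write/parse round-trip preserves genotypes in both dialects", {
  sim <- corpus_sim(11L)
  for (d in c("compact", "linkage")) {
    lines <- write_pedigree(sim$pedigree, file = NULL, dialect = d)
    ped2 <- parse_pedigree(lines, dialect = d)
    expect_identical(ped2$geno, sim$pedigree$geno)
    expect_identical(ped2$members, sim$pedigree$members)
  }
})

test_that("Mendelian check flags exactly the per-site impossibilities", {
  mk <- function(gf, gm, gc) {
    pedigree(id = c("f", "m", "c"), father = c(NA, NA, "f"),
             mother = c(NA, NA, "m"), geno = rbind(gf, gm, gc))
  }
  expect_equal(nrow(check_mendelian_consistency(mk(0L, 0L, 2L))), 1L)
  expect_equal(nrow(check_mendelian_consistency(mk(0L, 0L, 1L))), 1L)
  for (gc in 0:2) {
    expect_equal(nrow(check_mendelian_consistency(mk(2L, 2L, gc))), 0L)
  }
  expect_equal(nrow(check_mendelian_consistency(mk(1L, 0L, 2L))), 0L)
  expect_equal(nrow(check_mendelian_consistency(mk(1L, 0L, 0L))), 1L)
})

test_that("count_recombinations scores mosaics and localizes breakpoints", {
  ped <- pedigree(id = c("f", "m", "c"), father = c(NA, NA, "f"),
                  mother = c(NA, NA, "m"),
                  geno = rbind(c(2, 2), c(0, 0), c(2, 0)))
  phases1 <- list(f = haplotype_pair(c(1, 1), c(0, 0)),
                  m = haplotype_pair(c(0, 0), c(0, 0)),
                  c = haplotype_pair(c(1, 0), c(0, 0)))
  r1 <- count_recombinations(ped, phases1)
  expect_equal(r1$k, 1L)
  expect_equal(r1$events$child, "c")
  expect_equal(r1$events$parent, "f")
  expect_equal(c(r1$events$from_site, r1$events$to_site), c(1L, 2L))

  # the alternative father phasing explains the same child for free
  phases0 <- phases1
  phases0$f <- haplotype_pair(c(1, 0), c(0, 1))
  expect_equal(count_recombinations(ped, phases0)$k, 0L)

  # swapping h1/h2 of any single member never changes the count
  for (u in ped$members$id) {
    sw <- phases1
    sw[[u]] <- haplotype_pair(sw[[u]]$h2, sw[[u]]$h1)
    expect_equal(count_recombinations(ped, sw)$k, r1$k)
  }
})

test_that("planted configurations are witnesses: count <= planted", {
  for (s in 1:20) {
    sim <- corpus_sim(s)
    expect_phases_consistent(sim$pedigree, sim$phases)
    cnt <- count_recombinations(sim$pedigree, sim$phases)
    expect_lte(cnt$k, sim$k_planted)
  }
})

test_that("write_haplotypes emits rows and a deterministic event block", {
  cfg <- list(
    phases = list(u = haplotype_pair(c(1, 0), c(0, 1))),
    events = data.frame(child = "c", parent = "f", from_site = 1L,
                        to_site = 2L, stringsAsFactors = FALSE),
    k = 1L)
  lines <- write_haplotypes(cfg, file = NULL)
  expect_equal(lines[1], "u\t10\t01")
  expect_equal(lines[2], "#events\tk=1")
  expect_equal(lines[3], "c\tf\t(1,2)")

  cfg$events <- cfg$events[0, ]
  cfg$k <- 0L
  lines0 <- write_haplotypes(cfg, file = NULL)
  expect_equal(lines0[length(lines0)], "#events\tk=0")
})
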