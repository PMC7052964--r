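test_that("expansion ratios match hand computation", {
  tab <- make_count_table(1, 5, 3,
                          planted = tibble::tibble(orthogroup = 1, species = 1, count = 4))
  res <- expansion_ratios(tab)
  top <- res[res$orthogroup == "OG0001" & res$species == "sp1", ]
  expect_equal(top$mean_count, 1.6)
  expect_equal(top$ratio, 2.5)
  expect_true(top$flagged)
  # uniform counts: ratio 1 everywhere, nothing flagged
  uni <- expansion_ratios(make_count_table(1, 5, 4, background = function(n) rep(2L, n)))
  expect_true(all(uni$ratio == 1))
  expect_false(any(uni$flagged))
  # count 2 against four zeros: mean 0.4, ratio 5
  tab2 <- tibble::tibble(orthogroup = "OG1", sp1 = 2L, sp2 = 0L, sp3 = 0L,
                         sp4 = 0L, sp5 = 0L)
  r2 <- expansion_ratios(tab2)
  expect_equal(r2$ratio[r2$species == "sp1"], 5)
})

test_that("ratios support focal and averaging subsets and drop zero means", {
  tab <- tibble::tibble(orthogroup = c("OG1", "OG2"),
                        sp1 = c(4L, 0L), sp2 = c(1L, 0L), out1 = c(1L, 0L))
  res <- expansion_ratios(tab, focal_species = c("sp1", "sp2"))
  expect_setequal(unique(res$species), c("sp1", "sp2"))
  expect_false("OG2" %in% res$orthogroup)  # zero-mean group skipped
  # averaging over a subset changes the denominator
  res2 <- expansion_ratios(tab, focal_species = "sp1",
                           averaging_species = c("sp1", "sp2"))
  expect_equal(res2$ratio[res2$orthogroup == "OG1"], 4 / 2.5)
  expect_error(expansion_ratios(tab, focal_species = "spX"), "unknown species")
})

test_that("ratio output is invariant to row and column order", {
  tab <- make_count_table(6, 4, 8, planted = tibble::tibble(
    orthogroup = c(2, 5), species = c(3, 1), count = c(6L, 3L)))
  res <- expansion_ratios(tab)
  shuffled <- tab[sample.int(nrow(tab)), c(1, 1 + sample.int(4))]
  res2 <- expansion_ratios(shuffled)
  key <- function(d) d[order(d$orthogroup, d$species), ]
  expect_equal(key(as.data.frame(res2)), key(as.data.frame(res)),
               ignore_attr = TRUE)
})

test_that("hypergeometric tail is exact against enumeration and phyper", {
  expect_equal(hypergeom_tail(3, 3, 4, 10), 4 / 120, tolerance = 1e-12)
  expect_equal(hypergeom_tail(0, 5, 3, 12), 1)
  expect_equal(hypergeom_tail(1, 1, 4, 10), 0.4, tolerance = 1e-12)
  for (case in list(c(2, 5, 6, 11), c(1, 3, 3, 9), c(4, 6, 7, 12))) {
    expect_equal(hypergeom_tail(case[1], case[2], case[3], case[4]),
                 oracle_hypergeom_tail(case[1], case[2], case[3], case[4]),
                 tolerance = 1e-12)
  }
  # independent cross-check against R's own distribution function on a grid
  grid <- expand.grid(k = 0:6, n = c(4, 9), K = c(3, 11), N = 25)
  grid <- grid[grid$k <= pmin(grid$n, grid$K), ]
  got <- hypergeom_tail(grid$k, grid$n, grid$K, grid$N)
  want <- stats::phyper(grid$k - 1, grid$K, grid$N - grid$K, grid$n,
                        lower.tail = FALSE)
  expect_equal(got, want, tolerance = 1e-12)
  expect_error(hypergeom_tail(5, 3, 4, 10), "<=")
})

test_that("hypergeometric tail is monotone in k", {
  p <- hypergeom_tail(0:5, 5, 6, 15)
  expect_true(all(diff(p) <= 0))
})

test_that("GO enrichment reproduces the worked example and Bonferroni rules", {
  pop <- sprintf("g%02d", 1:10)
  g2g <- tibble::tibble(gene = pop[1:4], term = "T")
  res <- go_enrichment(pop[1:3], pop, g2g)
  expect_equal(res$p_raw, 4 / 120, tolerance = 1e-12)
  expect_equal(res$p_bonferroni, 4 / 120, tolerance = 1e-12)
  expect_true(res$significant)
  # two tested terms double the corrected p
  g2g2 <- dplyr::bind_rows(g2g, tibble::tibble(gene = pop[1:4], term = "U"))
  res2 <- go_enrichment(pop[1:3], pop, g2g2)
  expect_equal(res2$p_bonferroni, rep(2 * 4 / 120, 2), tolerance = 1e-12)
  # study == population: every p_raw is 1
  res3 <- go_enrichment(pop, pop, g2g)
  expect_equal(res3$p_raw, 1)
  expect_error(go_enrichment(c(pop[1], "stranger"), pop, g2g), "absent")
  expect_true(all(res2$p_bonferroni >= res2$p_raw))
})

test_that("planted expansions are always flagged; null tables are self-consistent", {
  # planted counts >= 3 in a 5-species all-1 background exceed 2x the mean
  planted <- tibble::tibble(orthogroup = c(3, 8, 14), species = c(1, 4, 2),
                            count = c(3L, 6L, 10L))
  tab <- make_count_table(10, 5, 20, planted = planted)
  res <- expansion_ratios(tab)
  for (i in seq_len(nrow(planted))) {
    row <- res[res$orthogroup == sprintf("OG%04d", planted$orthogroup[i]) &
                 res$species == paste0("sp", planted$species[i]), ]
    expect_true(row$flagged)
  }
  # random null: flag decisions equal direct recomputation on the same draws
  null_tab <- make_count_table(11, 5, 200,
                               background = function(n) rpois(n, 1) + 1L)
  res0 <- expansion_ratios(null_tab)
  m <- as.matrix(null_tab[, -1])
  direct <- as.vector(m / rowMeans(m) >= 2)
  long_direct <- tibble::tibble(
    orthogroup = rep(null_tab$orthogroup, 5),
    species = rep(colnames(m), each = nrow(m)),
    flagged = direct)
  joined <- dplyr::inner_join(as.data.frame(res0), long_direct,
                              by = c("orthogroup", "species"))
  expect_equal(joined$flagged.x, joined$flagged.y)
})

test_that("the combined screen feeds flagged families into enrichment", {
  tab <- make_count_table(12, 5, 10,
                          planted = tibble::tibble(orthogroup = 2, species = 1, count = 6))
  og_genes <- tibble::tibble(
    orthogroup = rep(sprintf("OG%04d", 1:10), each = 2),
    gene = sprintf("g%02d", 1:20))
  g2g <- tibble::tibble(gene = c("g03", "g04", "g11"), term = "GO:0001")
  out <- expansion_screen(tab, og_genes, g2g)
  expect_setequal(out$study_genes, c("g03", "g04"))  # genes of OG0002
  expect_equal(out$enrichment$study_hits, 2)
  expect_equal(out$enrichment$population_hits, 3)
})
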