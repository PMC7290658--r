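test_that("BH adjustment reproduces hand-computed and degenerate cases", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)),
               c(0.04, 0.04, 0.04, 0.04))
  expect_equal(bh_adjust(0.37), 0.37) # m = 1: unchanged
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("BH equals the step-up oracle and preserves significance order", {
  set.seed(23)
  for (k in 1:10) {
    p <- runif(sample(3:50, 1))
    adj <- bh_adjust(p)
    expect_equal(adj, oracle_bh(p))
    expect_true(all(adj >= p - 1e-12))
    expect_true(all(diff(adj[order(p)]) >= -1e-12))
  }
})

test_that("filtering keeps inclusive boundaries and labels directions", {
  tbl <- tibble::tibble(
    gene_id = c("at_cut", "below_lfc", "up_strong", "zero"),
    log2fc = c(0.8, 0.79, 2.5, 0),
    pvalue = c(1e-4, 1e-6, 1e-8, 1e-6),
    padj = c(0.05, 0.001, 1e-6, 1e-4)
  )
  kept <- filter_deg(tbl, deg_thresholds())
  expect_setequal(kept$gene_id, c("at_cut", "up_strong"))
  expect_equal(kept$direction[kept$gene_id == "at_cut"], "up")
  # the default cutoff corresponds to a 1.74-fold linear change
  expect_equal(round(2^0.8, 2), 1.74)
})

test_that("padj is recomputed over the full table when missing", {
  tbl <- tibble::tibble(gene_id = paste0("g", 1:4),
                        log2fc = c(2, -2, 1, -1),
                        pvalue = c(0.01, 0.02, 0.03, 0.04))
  kept <- filter_deg(tbl, deg_thresholds(max_padj = 0.04))
  expect_equal(kept$padj, rep(0.04, 4)) # BH over m = 4
})

test_that("relaxing either threshold never drops a previously kept gene", {
  set.seed(37)
  tbl <- tibble::tibble(gene_id = sprintf("g%03d", 1:300),
                        log2fc = rnorm(300, 0, 1.2),
                        pvalue = runif(300)^2)
  strict <- filter_deg(tbl, deg_thresholds(1.0, 0.05))
  relaxed_lfc <- filter_deg(tbl, deg_thresholds(0.5, 0.05))
  relaxed_p <- filter_deg(tbl, deg_thresholds(1.0, 0.2))
  expect_true(all(strict$gene_id %in% relaxed_lfc$gene_id))
  expect_true(all(strict$gene_id %in% relaxed_p$gene_id))
})

test_that("disjoint significant sets give an empty classification", {
  a <- tibble::tibble(gene_id = c("g1", "g2"), log2fc = c(1, -1),
                      direction = c("up", "down"))
  b <- tibble::tibble(gene_id = c("g3", "g4"), log2fc = c(1, -1),
                      direction = c("up", "down"))
  cl <- classify_opposing(a, b)
  expect_equal(cl$overlap, 0)
  expect_true(all(cl$summary$n == 0))
})

test_that("swapping the contrasts mirrors the opposing quadrants and fixes the concordant ones", {
  set.seed(51)
  mk <- function(n, ids) tibble::tibble(
    gene_id = ids, log2fc = rnorm(n, 0, 2),
    direction = NA) |>
    dplyr::mutate(direction = ifelse(log2fc > 0, "up", "down"))
  ids <- sprintf("g%02d", 1:30)
  a <- mk(30, ids); b <- mk(30, ids)
  cl <- glance(classify_opposing(a, b))
  swapped <- glance(classify_opposing(b, a))
  expect_equal(swapped$down_a_up_b, cl$up_a_down_b)
  expect_equal(swapped$up_a_down_b, cl$down_a_up_b)
  expect_equal(swapped$up_both, cl$up_both)
  expect_equal(swapped$down_both, cl$down_both)
})

test_that("row order of the inputs does not change the classification", {
  set.seed(52)
  ids <- sprintf("g%02d", 1:25)
  a <- tibble::tibble(gene_id = ids, log2fc = rnorm(25, 0, 2)) |>
    dplyr::mutate(direction = ifelse(log2fc > 0, "up", "down"))
  b <- tibble::tibble(gene_id = ids, log2fc = rnorm(25, 0, 2)) |>
    dplyr::mutate(direction = ifelse(log2fc > 0, "up", "down"))
  cl1 <- classify_opposing(a, b)
  cl2 <- classify_opposing(a[sample(25), ], b[sample(25), ])
  expect_identical(cl1$genes, cl2$genes)
})

test_that("duplicate gene ids are rejected", {
  dup <- tibble::tibble(gene_id = c("g1", "g1"), log2fc = c(1, 2),
                        direction = c("up", "up"))
  ok <- tibble::tibble(gene_id = "g2", log2fc = 1, direction = "up")
  expect_error(classify_opposing(dup, ok), "duplicate")
})

test_that("planted opposing regulation is recovered exactly from simulated tables", {
  deg <- generate_deg_tables(deg_sim_params(seed = 3L))
  cl <- classify_opposing(filter_deg(deg$contrast_a), filter_deg(deg$contrast_b))
  truth <- deg$planted[deg$planted$planted, ]
  expect_setequal(cl$genes$gene_id, truth$gene_id)
  expect_setequal(cl$genes$gene_id[cl$genes$quadrant == "down_a_up_b"],
                  truth$gene_id[truth$quadrant == "down_a_up_b"])
  # recovered quadrants match the planted labels gene by gene
  merged <- merge(cl$genes, truth, by = "gene_id")
  expect_true(all(merged$quadrant.x == merged$quadrant.y))
})
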