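test_that("Venn regions enumerate membership patterns exactly", {
  r <- venn_regions(list(A = c("1", "2"), B = c("2", "3")),
                    universe = as.character(1:4))
  expect_equal(region_list(r, "10"), "1")
  expect_equal(region_list(r, "01"), "3")
  expect_equal(region_list(r, "11"), "2")

  # disjoint sets have no intersection region
  r2 <- venn_regions(list(A = c("1", "2"), B = c("3", "4")),
                     universe = as.character(1:4))
  expect_false("11" %in% r2$pattern)

  expect_error(venn_regions(list(A = "x"), universe = "y"), "universe")
})

test_that("regions partition the union and match brute force", {
  withr::with_seed(19, {
    uni <- sprintf("g%04d", 1:1000)
    for (i in 1:5) {
      sets <- lapply(1:3, function(j) sample(uni, 100))
      names(sets) <- c("A", "B", "C")
      r <- venn_regions(sets, uni)
      oracle <- oracle_venn(sets)
      expect_equal(length(r$genes), length(oracle))
      for (p in r$pattern) {
        expect_equal(region_list(r, p), oracle[[p]])
      }
      # partition: pairwise disjoint, union equals union of inputs
      all_genes <- unlist(r$genes)
      expect_false(anyDuplicated(all_genes) > 0)
      expect_setequal(all_genes, unique(unlist(sets)))
    }
  })
})

test_that("wild-type sets follow the basal/induced/EGF-dependence mapping", {
  uni <- as.character(1:10)
  # one gene per membership pattern
  basal <- c("1", "3", "5", "7")
  induced <- c("2", "3", "6", "7")
  egf <- c("4", "5", "6", "7")
  wt <- build_wt_sets(basal, induced, egf, uni)
  expect_setequal(wt$sets$sets$set1, "5")          # basal & egf, not induced
  expect_setequal(wt$sets$sets$set2, "1")          # basal only
  expect_setequal(wt$sets$sets$set3, c("3", "7"))  # basal & induced
  expect_setequal(wt$sets$sets$set4, "6")          # induced & egf, not basal

  # identical inputs collapse everything into set3
  same <- build_wt_sets(basal, basal, basal, uni)
  expect_length(same$sets$sets$set1, 0)
  expect_length(same$sets$sets$set2, 0)
  expect_length(same$sets$sets$set4, 0)
  expect_setequal(same$sets$sets$set3, basal)
})

test_that("mutant sets classify the chronic pattern crossed with EGF", {
  uni <- as.character(1:20)
  pten <- c("1", "2", "5", "6")
  pik <- c("1", "2", "3", "4")
  induced <- c("7", "8", "9")
  egf <- c("1", "3", "5", "7")
  m <- build_mutant_sets(pten, pik, induced, egf, uni)
  s <- m$sets$sets
  expect_setequal(s$A, "1")   # both mutants, EGF-dependent
  expect_setequal(s$B, "2")   # both mutants, EGF-insensitive
  expect_setequal(s$C, "3")
  expect_setequal(s$D, "4")
  expect_setequal(s$E, "5")
  expect_setequal(s$F, "6")
  expect_setequal(s$G, "7")   # induced only, EGF-dependent
  expect_setequal(s$H, c("8", "9"))
  # A-H are pairwise disjoint
  expect_false(anyDuplicated(unlist(s)) > 0)
})

test_that("the coherence filter applies the PIP3 sign logic", {
  mk <- function(signs, genes = "g1") {
    nm <- c("PTEN_chronic", "PIK3CA_chronic", "A66_vs_WT", "A66_noEGF",
            "PTEN_induced", "PIK3CA_induced")
    out <- lapply(seq_along(nm), function(i) {
      tibble::tibble(gene_id = genes, significant = signs[[i]] != 0,
                     sign = signs[[i]])
    })
    names(out) <- nm
    out
  }
  up <- coherence_filter(mk(list(1, 1, -1, -1, 1, 1)))
  expect_equal(up$coherent_up, "g1")
  expect_length(up$coherent_down, 0)

  down <- coherence_filter(mk(list(-1, -1, 1, 1, -1, -1)))
  expect_equal(down$coherent_down, "g1")

  # mutants disagreeing excludes the gene
  mixed <- coherence_filter(mk(list(1, -1, -1, -1, 1, 1)))
  expect_length(mixed$coherent_up, 0)
  expect_length(mixed$coherent_down, 0)

  # a single non-significant comparison excludes the gene
  ns <- coherence_filter(mk(list(1, 1, -1, 0, 1, 1)))
  expect_length(ns$coherent_up, 0)

  o <- mk(list(1, 1, -1, -1, 1, 1))
  expect_error(coherence_filter(o[-1]), "PTEN_chronic")
})

test_that("coherence output is contained in every significant set", {
  withr::with_seed(31, {
    genes <- sprintf("g%03d", 1:200)
    nm <- c("PTEN_chronic", "PIK3CA_chronic", "A66_vs_WT", "A66_noEGF",
            "PTEN_induced", "PIK3CA_induced")
    outcomes <- lapply(nm, function(x) {
      s <- sample(c(-1, 0, 1), 200, replace = TRUE)
      tibble::tibble(gene_id = genes, significant = s != 0, sign = s)
    })
    names(outcomes) <- nm
    coh <- coherence_filter(outcomes)
    both <- union(coh$coherent_up, coh$coherent_down)
    for (o in outcomes) {
      expect_true(all(both %in% o$gene_id[o$significant]))
    }

    # relabelling genes permutes the output identically
    relab <- setNames(sprintf("x%03d", 1:200), genes)
    outcomes2 <- lapply(outcomes, function(o) {
      o$gene_id <- unname(relab[o$gene_id])
      o
    })
    coh2 <- coherence_filter(outcomes2)
    expect_setequal(coh2$coherent_up, unname(relab[coh$coherent_up]))
    expect_setequal(coh2$coherent_down, unname(relab[coh$coherent_down]))
  })
})
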