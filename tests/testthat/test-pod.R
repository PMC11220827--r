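# Point-of-departure derivation: pathway aggregation, selection rules and
# the safety-factor chain.

test_that("pathway medians aggregate passing genes only and apply the gene filter", {
  genes <- data.frame(gene_id = c("g1", "g2", "g3", "g4"),
                      bmd_uM = c(1, 2, 3, 100),
                      passes_filters = c(TRUE, TRUE, TRUE, FALSE))
  map <- data.frame(gene_id = paste0("g", 1:4), pathway_id = "pw1")
  out <- pathway_median_bmd(genes, map, min_genes = 3)
  expect_equal(out$median_bmd_uM, 2)
  expect_equal(out$n_genes_passing, 3L)

  # a pathway with 4 passing genes is excluded under the 5-gene filter
  genes$passes_filters <- TRUE
  expect_equal(nrow(pathway_median_bmd(genes, map, min_genes = 5)), 0)
  expect_equal(nrow(pathway_median_bmd(genes, map, min_genes = 4)), 1)

  # empty input is an empty summary, not an error
  expect_equal(nrow(pathway_median_bmd(genes[0, ], map)), 0)
  # unmapped gene is an error
  expect_error(pathway_median_bmd(genes, map[-1, ], 3), class = "ngra_validation_error")
})

test_that("pathway medians agree with a brute-force oracle on random tables", {
  set.seed(11)
  for (rep in 1:25) {
    n_pw <- sample(2:6, 1)
    genes <- data.frame(
      gene_id = sprintf("g%03d", 1:60),
      bmd_uM = exp(rnorm(60)),
      passes_filters = runif(60) < 0.7)
    map <- data.frame(gene_id = genes$gene_id,
                      pathway_id = sample(sprintf("pw%d", 1:n_pw), 60, TRUE))
    min_g <- sample(3:5, 1)
    out <- pathway_median_bmd(genes, map, min_g)
    # independent oracle: explicit loop over pathways
    merged <- merge(genes[genes$passes_filters, ], map, by = "gene_id")
    for (pw in unique(map$pathway_id)) {
      v <- merged$bmd_uM[merged$pathway_id == pw]
      if (length(v) >= min_g) {
        expect_equal(out$median_bmd_uM[out$pathway_id == pw], median(v))
      } else {
        expect_false(pw %in% out$pathway_id)
      }
    }
    # 5-gene output is a subset of 3-gene output, with a >= lowest median
    o3 <- pathway_median_bmd(genes, map, 3)
    o5 <- pathway_median_bmd(genes, map, 5)
    expect_true(all(o5$pathway_id %in% o3$pathway_id))
    if (nrow(o5) && nrow(o3)) {
      expect_gte(min(o5$median_bmd_uM), min(o3$median_bmd_uM))
    }
  }
})

test_that("lowest median BMD picks the minimum with a logged lexicographic tie-break", {
  s <- data.frame(pathway_id = c("b", "a", "c"),
                  n_genes_passing = c(3L, 3L, 3L),
                  median_bmd_uM = c(0.5, 2, 0.5))
  lo <- lowest_median_bmd(s)
  expect_equal(lo$pathway_id, "b")
  expect_true(attr(lo, "tie"))
  one <- lowest_median_bmd(s[2, , drop = FALSE])
  expect_equal(one$pathway_id, "a")
  expect_false(attr(one, "tie"))
  expect_error(lowest_median_bmd(s[0, ]), class = "ngra_validation_error")
})

test_that("fold ratios round half-up to integers at 2-fold and above", {
  expect_equal(bmd_fold_ratio(33.1, 0.040), 828)
  expect_equal(bmd_fold_ratio(0.038, 0.0065), 6)
  expect_equal(bmd_fold_ratio(30.0, 15.7), 2)
  expect_equal(bmd_fold_ratio(3.3, 3.3), 1)
  expect_equal(bmd_fold_ratio(1.2, 1), 1.2)
  expect_error(bmd_fold_ratio(-1, 2), class = "ngra_validation_error")
})

test_that("PoD selection is governed by functional activity, not binding", {
  panel <- fixture_panel("daidzein")
  sel <- select_pod(panel)
  expect_equal(sel$assay_id, "calux_eralpha")
  expect_equal(sel$value_nM, 100)
  expect_equal(sel$s9, "plus")
  log <- attr(sel, "selection_log")
  # the lower ER-beta binding LOEC (3.2 nM) must be excluded, with a reason
  expect_true(any(grepl("pharmacology_erbeta", log) & grepl("supporting", log)))
  expect_true(any(grepl("S9 pair", log)))

  gen <- select_pod(fixture_panel("genistein"))
  expect_equal(gen$value_nM, 5.2)
  expect_equal(gen$s9, "plus")
})

test_that("PoD selection is invariant to panel row order and handles degenerate panels", {
  panel <- fixture_panel("daidzein")
  set.seed(3)
  for (i in 1:5) {
    shuffled <- panel[sample(nrow(panel)), ]
    expect_equal(select_pod(shuffled)$value_nM, 100)
  }
  one <- tiny_panel(loec = 42)
  expect_equal(select_pod(one)$value_nM, 42)
  binding_only <- assay_panel(data.frame(
    chemical_id = "x", assay_id = "bind", endpoint_class = "receptor_binding",
    measure = "Ki", value_nM = 1))
  expect_error(select_pod(binding_only), class = "ngra_no_functional_result")
})

test_that("the safety-factor chain divides at full precision and displays as printed", {
  pod <- derive_pod(100)
  expect_equal(pod$noec_nM, 100 / 3)
  expect_equal(pod$safe_internal_nM, 100 / 3 / 3.3)
  expect_equal(display_conc(pod$noec_nM), 33)
  expect_equal(display_conc(pod$safe_internal_nM), 10)
  expect_lt(pod$safe_internal_nM, pod$noec_nM)
  expect_lt(pod$noec_nM, pod$loec_nM)

  gen <- derive_pod(5.2, sf_intraindividual = 1)
  expect_equal(display_conc(gen$noec_nM), 1.73)

  ident <- derive_pod(7, 1, 1)
  expect_equal(ident$safe_internal_nM, 7)
  expect_error(derive_pod(tiny_panel()[1, ] |> transform(measure = "IC50")),
               class = "ngra_validation_error")
})

test_that("assay panels validate the measure/endpoint-class matrix", {
  bad <- data.frame(chemical_id = "x", assay_id = "a",
                    endpoint_class = "cell_stress", measure = "Ki", value_nM = 1)
  expect_error(assay_panel(bad), class = "ngra_validation_error")
  expect_error(assay_panel(transform(bad, measure = "LOEC", value_nM = -1)),
               class = "ngra_validation_error")
  ok <- assay_panel(transform(bad, measure = "LOEC"))
  expect_s3_class(ok, "assay_panel")
})

test_that("selection rules accept a custom governing-class set", {
  panel <- fixture_panel("daidzein")
  # restricting governance to enzyme inhibition promotes the TTR LOEC
  sel <- select_pod(panel, governing_classes = "enzyme_inhibition")
  expect_equal(sel$assay_id, "ttr_binding")
  expect_equal(sel$value_nM, 1000)
  expect_error(select_pod(panel, governing_classes = "not_a_class"))
})
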