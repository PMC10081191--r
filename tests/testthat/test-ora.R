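test_that("input mapping splits found/missing, collapses duplicates and rejects empty mappings", {
  kb <- small_ora_kb()
  m <- map_input_ids(kb, c("C00001", "C00002", "C00009"))
  expect_identical(m$found, c("C00001", "C00002"))
  expect_identical(m$missing, "C00009")
  expect_identical(m$b, 2L)
  expect_warning(m2 <- map_input_ids(kb, c("C00001", "C00001", "C00002")),
                 "duplicated")
  expect_identical(m2$b, 2L)
  expect_warning(m3 <- map_input_ids(kb, c("C00001", "banana")),
                 "not valid KEGG C-numbers")
  expect_identical(m3$invalid, "banana")
  expect_error(map_input_ids(kb, c("C00900", "C00901")),
               class = "metago_analysis_error")
})

test_that("hypergeometric upper tail matches hand-derived and published values", {
  # published nucleoside-salvage example: the printed p-value
  expect_equal(hypergeom_upper_tail(13, 61, 2151, 62), 4.218424e-09,
               tolerance = 1e-6)
  # the narrated a = N - b parameterization agrees within 2%
  expect_equal(hypergeom_upper_tail(13, 61, 2150, 62),
               hypergeom_upper_tail(13, 61, 2151, 62), tolerance = 0.02)
  # P(X >= 0) = 1 for any frame
  expect_identical(hypergeom_upper_tail(0, 5, 3, 4), 1)
  expect_identical(hypergeom_upper_tail(0, 1, 1, 0), 1)
  # 2 successes, 2 failures, draw 2: exactly 1 of C(4,2)=6 draws has both
  expect_equal(hypergeom_upper_tail(2, 2, 2, 2), 1 / 6,
               tolerance = 1e-12)
})

test_that("hypergeometric upper tail equals exhaustive draw enumeration for y+a <= 12", {
  for (n in 1:12) {
    for (y in 0:n) {
      a <- n - y
      for (b in 0:n) {
        for (x in 0:min(y, b)) {
          expect_equal(hypergeom_upper_tail(x, y, a, b),
                       hyper_tail_enum(x, y, a, b), tolerance = 1e-12,
                       label = sprintf("x=%d y=%d a=%d b=%d", x, y, a, b))
        }
      }
    }
  }
})

test_that("the upper tail is monotone in x and upper-tail differences sum to one", {
  for (frame in list(c(5, 7, 6), c(8, 4, 8), c(61, 11, 20))) {
    y <- frame[1]; a <- frame[2]; b <- frame[3]
    p <- vapply(0:min(y, b), hypergeom_upper_tail, numeric(1),
                y = y, a = a, b = b)
    expect_true(all(diff(p) <= 1e-15))
    # P[X = x] reconstructed from successive tails must sum to 1
    expect_equal(sum(diff(-c(p, 0))), 1, tolerance = 1e-12)
  }
})

test_that("domain violations are rejected", {
  expect_error(hypergeom_upper_tail(3, 2, 5, 5),
               class = "metago_domain_error")   # x > y
  expect_error(hypergeom_upper_tail(1, 2, 1, 5),
               class = "metago_domain_error")   # b > y + a
  expect_error(hypergeom_upper_tail(-1, 2, 1, 1),
               class = "metago_domain_error")
  expect_error(hypergeom_upper_tail(0.5, 2, 1, 1),
               class = "metago_domain_error")
})

test_that("relevance filters implement the three rules with strict boundaries", {
  # defaults: x >= 3, gene_count >= 3, x > 0.05 * y
  expect_true(apply_filters(13, 61, 5))          # 13 >= 3, 5 >= 3, 13 > 3.05
  expect_true(apply_filters(3, 10, 3))           # boundary x = 3 passes
  expect_false(apply_filters(2, 10, 10))         # overlap below 3
  expect_false(apply_filters(13, 61, 2))         # too few genes
  expect_false(apply_filters(4, 100, 10))        # 4 is not > 5
  expect_false(apply_filters(5, 100, 10))        # x = 0.05*y not strict
  expect_true(apply_filters(6, 100, 10))
  expect_false(apply_filters(3, 60, 10))         # x = ceil(0.05*60) = 3, not > 3
  expect_true(apply_filters(4, 60, 10))
})

test_that("BH adjustment matches the step-up formula and its properties", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.5), 0.5)
  expect_identical(bh_fdr(numeric(0)), numeric(0))
  set.seed(1)
  for (i in 1:20) {
    p <- runif(sample(1:40, 1))
    q <- bh_fdr(p)
    expect_equal(q, bh_oracle(p), tolerance = 1e-12)
    expect_true(all(q >= p - 1e-15))
    expect_true(all(q <= 1))
    expect_true(all(diff(q[order(p)]) >= -1e-15))
  }
})

test_that("run_ora reproduces enumerated p-values on the six-compound fixture", {
  kb <- small_ora_kb()
  rep <- run_ora(kb, c("C00001", "C00002", "C00003"), min_overlap = 1,
                 min_genes = 1, min_overlap_fraction = 0)
  res <- rep$results
  a_row <- res[res$term_id == "GO:1000001", ]
  b_row <- res[res$term_id == "GO:1000002", ]
  # P[X >= 3 | y=3, a=3, b=3] = 1/C(6,3) = 0.05
  expect_identical(c(a_row$x, a_row$y, a_row$a, a_row$b), c(3L, 3L, 3L, 3L))
  expect_equal(a_row$p_value, 0.05, tolerance = 1e-12)
  expect_identical(a_row$overlap_compounds[[1]],
                   c("C00001", "C00002", "C00003"))
  # B always receives at least one draw (only 2 failures for 3 draws)
  expect_equal(b_row$p_value, 1, tolerance = 1e-12)
  # sorted by p then term_id
  expect_identical(res$term_id[1], "GO:1000001")
  expect_true(!is.unsorted(res$p_value))
})

test_that("an input disjoint from every term yields x = 0 and p = 1 everywhere", {
  kb <- small_ora_kb()
  kb$universe <- c(kb$universe, "C00099")
  kb$background_n <- 7L
  rep <- run_ora(kb, "C00099", min_overlap = 1, min_genes = 1,
                 min_overlap_fraction = 0)
  expect_true(all(rep$results$x == 0L))
  expect_true(all(rep$results$p_value == 1))
})

test_that("default filters drop under-supported terms and FDR m is the filtered count", {
  kb <- small_ora_kb(gene_counts = c(A = 3L, B = 2L))
  rep <- run_ora(kb, c("C00001", "C00002", "C00003"))
  res <- rep$results
  expect_true(res$passed_filters[res$term_id == "GO:1000001"])
  expect_false(res$passed_filters[res$term_id == "GO:1000002"])
  # only the passing term enters BH: m = 1, q = p
  expect_equal(res$q_value[res$term_id == "GO:1000001"],
               res$p_value[res$term_id == "GO:1000001"])
  expect_true(is.na(res$q_value[res$term_id == "GO:1000002"]))
  # fdr_all_terms adjusts across every tested term
  rep2 <- run_ora(kb, c("C00001", "C00002", "C00003"),
                  fdr_all_terms = TRUE)
  expect_false(anyNA(rep2$results$q_value))
})

test_that("input order never changes any statistic", {
  kb <- small_ora_kb()
  ids <- c("C00001", "C00003", "C00005", "C00006")
  rep1 <- run_ora(kb, ids, min_overlap = 1, min_genes = 1,
                  min_overlap_fraction = 0)
  set.seed(9)
  for (i in 1:5) {
    repi <- run_ora(kb, sample(ids), min_overlap = 1, min_genes = 1,
                    min_overlap_fraction = 0)
    expect_identical(repi$results, rep1$results)
  }
})

test_that("the impact table floors p and reports -log10(p) per passing term", {
  kb <- small_ora_kb()
  rep <- run_ora(kb, c("C00001", "C00002", "C00003"), min_overlap = 1,
                 min_genes = 1, min_overlap_fraction = 0)
  it <- impact_table(rep)
  expect_identical(it$term_id, rep$results$term_id[
    rep$results$passed_filters])
  expect_equal(it$neg_log10_p[it$term_id == "GO:1000001"],
               -log10(0.05), tolerance = 1e-9)  # ~1.30103
  expect_equal(it$neg_log10_p[it$term_id == "GO:1000002"], 0)
  # the floor keeps the transform finite
  rep$results$p_value[1] <- 0
  expect_equal(impact_table(rep)$neg_log10_p[1], 300)
})

test_that("identifier maps translate upstream ids ahead of analysis", {
  map <- data.frame(from = c("5793", "312"), to = c("C00031", "C00001"))
  expect_identical(apply_id_map(c("5793", "312", "C00099"), map),
                   c("C00031", "C00001", "C00099"))
  # translation collapsing two sources onto one C-number deduplicates
  map2 <- data.frame(from = c("1", "2"), to = c("C00001", "C00001"))
  expect_identical(apply_id_map(c("1", "2"), map2), "C00001")
})

test_that("worked-example frame reproduces x=13, y=61, b=62 and the published p", {
  kb <- worked_example_kb()
  rep <- run_ora(kb, worked_example_input(), min_overlap = 1,
                 min_genes = 1, min_overlap_fraction = 0)
  row <- rep$results[rep$results$term_id == "GO:0043174", ]
  expect_identical(c(row$x, row$y, row$b), c(13L, 61L, 62L))
  expect_identical(row$a, kb$background_n - row$y)
  expect_equal(row$p_value, 4.218424e-09, tolerance = 1e-6)
  expect_identical(row$gene_count, 4L)
  # and it passes the default filters
  rep2 <- run_ora(kb, worked_example_input())
  expect_true(rep2$results$passed_filters[
    rep2$results$term_id == "GO:0043174"])
})
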