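toy_counts <- function() {
  tibble::tibble(protein = c("p1", "p2"),
                 yellow = c(400, 600),
                 red = c(1100, 1100),
                 brown = c(900, 900))
}

test_that("loading factors are column-total ratios with reference 1", {
  lf <- loading_factors(toy_counts(), reference = "yellow")
  expect_equal(setNames(lf$factor, lf$sample),
               c(yellow = 1, red = 2.2, brown = 1.8))
  # min-total default picks the smallest column, giving factors >= 1
  lf2 <- loading_factors(toy_counts())
  expect_equal(attr(lf2, "reference"), "yellow")
  expect_true(all(lf2$factor >= 1))
  # equal totals -> all ones
  eq <- tibble::tibble(protein = "p", a = 5, b = 5)
  expect_equal(loading_factors(eq)$factor, c(1, 1))
  expect_error(loading_factors(toy_counts(), "magenta"),
               class = "chromatophore_input_error")
  zero <- tibble::tibble(protein = "p", a = 0, b = 3)
  expect_error(loading_factors(zero, reference = "a"),
               class = "chromatophore_input_error")
})

test_that("loading normalization divides columns; reference unchanged", {
  norm <- normalize_loading(toy_counts(),
                            loading_factors(toy_counts(), "yellow"))
  expect_equal(norm$yellow, c(400, 600))
  expect_equal(norm$red, c(500, 500))
  expect_equal(norm$brown, c(500, 500))
  expect_error(normalize_loading(toy_counts(), c(yellow = 1)),
               class = "chromatophore_input_error")
})

test_that("abundance index is count / k_p * k_bar", {
  expect_equal(abundance_index(10, 20, 65.5), 32.75)
  expect_equal(abundance_index(7, 65.5, 65.5), 7)   # k_p = k_bar identity
  expect_equal(abundance_index(0, 13, 65.5), 0)
  expect_error(abundance_index(5, 0, 65.5),
               class = "chromatophore_input_error")
})

test_that("abundance_table composes the pipeline as hand computation", {
  prot <- tibble::tibble(id = c("p1", "p2"),
                         sequence = c("MKTAYR", "GGGG"))  # k_p = 2, 1
  counts <- tibble::tibble(protein = c("p1", "p2"),
                           s1 = c(10, 10), s2 = c(30, 10))
  ab <- abundance_table(counts, prot, reference = "s1")
  # totals 20 vs 40 -> factors 1, 2; k_bar = 1.5
  # p1 s1: 10/1 / 2 * 1.5 = 7.5 ; p2 s2: 10/2 / 1 * 1.5 = 7.5
  expect_equal(attr(ab, "k_bar"), 1.5)
  get <- function(p, s) ab$index[ab$protein == p & ab$sample == s]
  expect_equal(get("p1", "s1"), 7.5)
  expect_equal(get("p2", "s1"), 15)
  expect_equal(get("p1", "s2"), 11.25)
  expect_equal(get("p2", "s2"), 7.5)
  expect_equal(ab$index_int, sapply(ab$index, function(x) round(x + 1e-12)))
  # granule mode: no loading normalization
  ab2 <- abundance_table(counts, prot, normalize_loading = FALSE)
  expect_equal(ab2$normalized, ab2$count)
  expect_error(abundance_table(counts, prot[1, ]),
               "p2", class = "chromatophore_input_error")
})

test_that("single protein, factor 1, k_p = k_bar gives index = count", {
  prot <- tibble::tibble(id = "p1", sequence = "MKTAYR")
  counts <- tibble::tibble(protein = "p1", s1 = 5)
  ab <- abundance_table(counts, prot)
  expect_equal(ab$index, 5)
})

test_that("sample-wide rescaling leaves its normalized column unchanged", {
  counts <- toy_counts()
  ab1 <- abundance_table(counts,
                         tibble::tibble(id = c("p1", "p2"),
                                        sequence = c("MKTAYR", "GGGG")),
                         reference = "yellow")
  counts2 <- counts
  counts2$red <- counts2$red * 7
  ab2 <- abundance_table(counts2,
                         tibble::tibble(id = c("p1", "p2"),
                                        sequence = c("MKTAYR", "GGGG")),
                         reference = "yellow")
  expect_equal(ab2$index, ab1$index)
  lf1 <- loading_factors(counts, "yellow")
  lf2 <- loading_factors(counts2, "yellow")
  expect_equal(lf2$factor[lf2$sample == "red"],
               7 * lf1$factor[lf1$sample == "red"])
})

test_that("abundance indexing preserves within-sample ranking of count/k_p", {
  set.seed(11)
  prot <- make_proteome(20, seed = 3)
  kp <- digest_proteome(prot)$expected_peptides
  counts <- tibble::tibble(protein = prot$id,
                           s1 = rpois(20, 200), s2 = rpois(20, 300))
  ab <- abundance_table(counts, prot, reference = "s1")
  for (s in c("s1", "s2")) {
    sub <- ab[ab$sample == s, ]
    expect_equal(order(sub$index), order(sub$count / sub$k_p))
  }
})

test_that("category percentages sum to 100 and match hand arithmetic", {
  ab <- tibble::tibble(protein = c("a", "b", "c"),
                       sample = "s1", index = c(1, 1, 2))
  cats <- tibble::tibble(protein = c("a", "b", "c"),
                         category = c("x", "y", "z"))
  out <- category_percentages(ab, cats)
  expect_equal(sort(out$percent), c(25, 25, 50))
  expect_equal(sum(out$percent), 100)
  # one category -> 100%; unmapped -> uncharacterized
  out2 <- category_percentages(ab, cats[1, ])
  expect_equal(out2$percent[out2$category == "uncharacterized"], 75)
  expect_error(
    category_percentages(dplyr::mutate(ab, index = 0), cats),
    class = "chromatophore_input_error")
  expect_error(
    category_percentages(ab, dplyr::bind_rows(cats, cats[1, ])),
    class = "chromatophore_input_error")
})

test_that("contaminant filter partitions records exhaustively", {
  rec <- tibble::tibble(
    id = c("c1", "c2", "c3", "c4"),
    description = c("30S ribosomal protein S4, Vibrio sp.",
                    "Omega-crystallin",
                    "Trypsin precursor",
                    "reflectin A1"))
  out <- contaminant_filter(rec)
  expect_equal(out$removed$id, c("c1", "c3"))
  expect_equal(out$kept$id, c("c2", "c4"))
  expect_equal(nrow(out$kept) + nrow(out$removed), nrow(rec))
  expect_match(out$removed$matched_rule[1], "ribosomal")
  # empty rules = identity
  id <- contaminant_filter(rec, contaminant_rules(keywords = character()))
  expect_equal(id$kept, rec)
  # blocklist and malformed regex
  bl <- contaminant_filter(rec, contaminant_rules(keywords = character(),
                                                  blocklist = "c4"))
  expect_equal(bl$removed$matched_rule, "blocklist")
  expect_error(contaminant_rules(patterns = "("),
               class = "chromatophore_config_error")
})
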