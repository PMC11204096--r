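test_that("keyword categorization matches the documented examples", {
  s <- data.frame(
    gene_id = c("g1", "g2", "g3", "g4"),
    summary_text = c(
      "this receptor binds a chemokine ligand",
      "",
      "linked to mitochondrial metabolism and renal injury",
      "mitochondriation is not a word matching anything" # no whole-word hit
    ),
    stringsAsFactors = FALSE
  )
  out <- categorize_genes(s)
  expect_equal(out$categories[1], "inflammatory response")
  expect_equal(out$categories[2], "uncategorized")
  expect_setequal(strsplit(out$categories[3], ";")[[1]],
                  c("mitochondria", "kidney damage"))
  expect_equal(out$categories[4], "uncategorized")
})

test_that("categorization agrees with a naive token-scan oracle on random texts", {
  scheme <- default_keyword_scheme()
  vocab <- c(scheme$keyword, "podocyte", "glomerulus", "ligand", "binding",
             "rat", "kidney", "matrix", "chain", "system", "renal",
             "respiratory", "extracellular", "injury")
  set.seed(17)
  for (i in 1:500) {
    txt <- paste(sample(vocab, sample(3:12, 1), replace = TRUE), collapse = " ")
    got <- categorize_genes(
      data.frame(gene_id = "g", summary_text = txt, stringsAsFactors = FALSE),
      scheme
    )$categories
    expect_equal(got, oracle_categorize(txt, scheme), info = txt)
  }
})

test_that("categorization is idempotent, order-insensitive, and monotone in keywords", {
  scheme <- default_keyword_scheme()
  s <- data.frame(
    gene_id = sprintf("g%d", 1:3),
    summary_text = c("adipocyte differentiation factor",
                     "axon guidance and leukocyte adhesion",
                     "nothing relevant here"),
    stringsAsFactors = FALSE
  )
  out1 <- categorize_genes(s, scheme)
  expect_equal(categorize_genes(s, scheme), out1) # idempotent
  out2 <- categorize_genes(s, scheme[sample(nrow(scheme)), ])
  for (i in 1:3) { # keyword order may permute the joined string, not the set
    expect_setequal(strsplit(out1$categories[i], ";")[[1]],
                    strsplit(out2$categories[i], ";")[[1]])
  }
  # adding a keyword can only add categories
  grown <- rbind(scheme, data.frame(category = "kidney damage",
                                    keyword = "relevant"))
  out3 <- categorize_genes(s, grown)
  for (i in 1:3) {
    old <- strsplit(out1$categories[i], ";")[[1]]
    new <- strsplit(out3$categories[i], ";")[[1]]
    if (!identical(old, "uncategorized")) expect_true(all(old %in% new))
  }
  expect_equal(out3$categories[3], "kidney damage")
})

test_that("2^-dCT follows the closed form and its reciprocal identity", {
  expect_equal(relative_abundance_2dct(25, 25), 1.0)
  expect_equal(relative_abundance_2dct(25, 22), 0.125)
  expect_equal(relative_abundance_2dct(20, 23), 8.0)
  set.seed(12)
  for (i in 1:20) {
    a <- runif(1, 5, 40)
    b <- runif(1, 5, 40)
    expect_equal(relative_abundance_2dct(a, b) * relative_abundance_2dct(b, a),
                 1, tolerance = 1e-12)
  }
  expect_error(relative_abundance_2dct(46, 20), "outside the allowed range")
  expect_error(relative_abundance_2dct(0, 20), "outside the allowed range")
})

test_that("spike-in normalized Ct is the signed difference", {
  expect_equal(normalized_ct(20, 25), -5)
  expect_equal(normalized_ct(30, 30), 0)
  expect_equal(normalized_ct(30, 18.5), 11.5)
  expect_error(normalized_ct(50, 20), "outside the allowed range")
})

test_that("hematocrit and blood-to-plasma conversion enforce their domains", {
  expect_equal(hematocrit_percent(10, 10), 100)
  expect_equal(hematocrit_percent(4, 10), 40)
  expect_error(hematocrit_percent(0, 10), "outside the allowed range")
  expect_error(hematocrit_percent(11, 10), "cannot exceed")

  expect_equal(plasma_from_blood(60, 0), 60)
  expect_equal(plasma_from_blood(60, 0.4), 100)
  expect_true(is.finite(plasma_from_blood(60, 0.999)))
  expect_error(plasma_from_blood(60, 1), "outside the allowed range")
  # strictly increasing in the hematocrit fraction
  h <- seq(0, 0.9, by = 0.1)
  v <- vapply(h, function(f) plasma_from_blood(60, f), numeric(1))
  expect_true(all(diff(v) > 0))
})

test_that("qPCR replicate aggregation applies both normalizations", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "sample_id,assay_id,ct,is_spike_in,is_housekeeping",
    "s1,Hmbs,22.0,FALSE,TRUE",
    "s1,Hmbs,22.4,FALSE,TRUE",
    "s1,Pten,25.2,FALSE,FALSE",
    "s1,Pten,25.0,FALSE,FALSE",
    "s1,UniSp6,20.0,TRUE,FALSE",
    "s1,miR-205,24.0,FALSE,FALSE"
  ), p)
  q <- read_qpcr(p)
  out <- summarize_qpcr(q)
  pten <- out[out$assay_id == "Pten", ]
  expect_equal(pten$ct_mean, 25.1)
  expect_equal(pten$n_replicates, 2L)
  expect_equal(pten$replicate_sd, sd(c(25.2, 25.0)))
  expect_equal(pten$rel_abundance_2dct,
               relative_abundance_2dct(25.1, mean(c(22.0, 22.4))))
  mir <- out[out$assay_id == "miR-205", ]
  expect_equal(mir$normalized_ct, normalized_ct(20.0, 24.0))
  expect_true(is.na(out$rel_abundance_2dct[out$assay_id == "Hmbs"]))

  q2 <- q
  q2$is_housekeeping <- FALSE
  expect_error(summarize_qpcr(q2), "exactly one housekeeping")
})
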