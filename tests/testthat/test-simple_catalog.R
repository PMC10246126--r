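test_that("the default schema has the documented 49-subcategory composition", {
  s <- simple_sv_schema()
  expect_equal(nrow(s), 49)
  expect_equal(sum(s$qualifier == "fragile_site"), 2)
  expect_equal(sum(s$major_class == "deletion" & s$qualifier == "size_bin"), 18)
  expect_equal(sum(s$major_class == "tandem_duplication" & s$qualifier == "size_bin"), 18)
  expect_equal(sum(s$qualifier == "unbalanced_size_bin"), 3)
  expect_equal(sum(s$qualifier == "reciprocal_size_bin"), 5)
  expect_equal(sum(s$qualifier %in% c("foldback", "reciprocal", "unbalanced")), 3)
  expect_setequal(unique(s$signature), signature_names()[signature_names() != "BRAF fusion"])

  # bin unions pass through the printed signature cut-points
  del <- s[s$major_class == "deletion" & s$qualifier == "size_bin", ]
  expect_true(all(c(1e3, 5e3, 1e7) %in% del$size_min))
  td <- s[s$major_class == "tandem_duplication" & s$qualifier == "size_bin", ]
  expect_true(all(c(1e6, 2.5e6, 1e7) %in% td$size_min))
  ui <- s[s$qualifier == "unbalanced_size_bin", ]
  expect_true(all(c(5e4, 5e6) %in% ui$size_min))
  ri <- s[s$qualifier == "reciprocal_size_bin", ]
  expect_true(5e6 %in% ri$size_min)
})

test_that("inversion/translocation subtyping follows the pairing rules", {
  cfg <- catalog_config()
  # h2h + t2t with all four breakends pairable: one reciprocal inversion
  pair <- mk_calls(
    mk_call("chr1", 1e6, "chr1", 3e6, "h2hINV"),
    mk_call("chr1", 1e6 + 400, "chr1", 3e6 + 900, "t2tINV"))
  typed <- subtype_inversions_translocations(pair, cfg)
  expect_equal(nrow(typed), 1)
  expect_equal(typed$simple_type, "reciprocal_inversion")
  expect_equal(typed$size, 2e6)
  expect_equal(typed$n_junctions, 2L)

  # partners 1.5 kb apart do not pair: two separate inversions
  apart <- mk_calls(
    mk_call("chr1", 1e6, "chr1", 3e6, "h2hINV"),
    mk_call("chr1", 1e6 + 1500, "chr1", 3e6, "t2tINV"))
  expect_equal(nrow(subtype_inversions_translocations(apart, cfg)), 2)

  # lone inversion with a 300 bp gap: fold-back
  fb <- mk_calls(mk_call("chr1", 1e6, "chr1", 1e6 + 300, "h2hINV"))
  expect_equal(subtype_inversions_translocations(fb, cfg)$simple_type,
               "foldback_inversion")

  # lone 2 Mb t2t inversion: unbalanced inversion
  ui <- mk_calls(mk_call("chr1", 1e6, "chr1", 3e6, "t2tINV"))
  expect_equal(subtype_inversions_translocations(ui, cfg)$simple_type,
               "unbalanced_inversion")

  # TRA pair with pairable ends, opposite orientations: reciprocal translocation
  tra <- mk_calls(
    mk_call("chr1", 1e6, "chr2", 2e6, "TRA", strand1 = "+", strand2 = "-"),
    mk_call("chr1", 1e6 + 100, "chr2", 2e6 + 120, "TRA", strand1 = "-", strand2 = "+"))
  t2 <- subtype_inversions_translocations(tra, cfg)
  expect_equal(t2$simple_type, "reciprocal_translocation")
  # lone TRA: unbalanced
  lone <- mk_calls(mk_call("chr1", 1e6, "chr2", 2e6, "TRA"))
  expect_equal(subtype_inversions_translocations(lone, cfg)$simple_type,
               "unbalanced_translocation")
})

test_that("subcategory classification puts the fragile-site check first, then size bins", {
  g <- toy_genome()
  cfg <- catalog_config()
  schema <- simple_sv_schema()
  mk_typed <- function(...) {
    typed <- subtype_inversions_translocations(mk_calls(...), cfg)
    typed$subcategory <- classify_simple(typed, schema, g, cfg)
    typed
  }
  # 900 bp deletion outside fragile sites -> a sub-1 kb bin -> Del0
  t1 <- mk_typed(mk_call("chr1", 5e6, "chr1", 5e6 + 900, "DEL"))
  expect_match(t1$subcategory, "^DEL_")
  expect_equal(assignment_rules(schema)[[t1$subcategory]], "Del0")

  # 3 kb deletion -> 1-5 kb bin -> Del1
  t2 <- mk_typed(mk_call("chr1", 5e6, "chr1", 5e6 + 3000, "DEL"))
  expect_equal(assignment_rules(schema)[[t2$subcategory]], "Del1")

  # 50 kb deletion with a breakend inside the fragile site -> fragile-site DEL -> Del2
  t3 <- mk_typed(mk_call("chr1", 2.05e6, "chr1", 2.05e6 + 5e4, "DEL"))
  expect_equal(t3$subcategory, "DEL_fragile_site")
  expect_equal(assignment_rules(schema)[[t3$subcategory]], "Del2")

  # 20 Mb tandem duplication -> large-TD bin -> Large mixed
  gbig <- genome_model(data.frame(name = "chr1", length = 50e6))
  tdbig <- sv_calls(mk_call("chr1", 1e6, "chr1", 21e6, "DUP"), gbig)
  typed <- subtype_inversions_translocations(tdbig, cfg)
  typed$subcategory <- classify_simple(typed, schema, gbig, cfg)
  expect_equal(assignment_rules(schema)[[typed$subcategory]], "Large mixed")

  # nonpositive size is rejected
  zero <- data.frame(simple_type = "deletion", size = 0, chrom1 = "chr1",
                     pos1 = 1, chrom2 = "chr1", pos2 = 1)
  expect_error(classify_simple(zero, schema, g, cfg), "size")
})

test_that("every fuzzed simple SV maps to exactly one subcategory", {
  g <- toy_genome()
  cfg <- catalog_config()
  schema <- simple_sv_schema()
  with_seed_local(31, {
    types <- sample(c("DEL", "DUP", "h2hINV", "t2tINV", "TRA"), 400, TRUE)
    chrom1 <- sample(g$chromosomes$name, 400, TRUE)
    chrom2 <- ifelse(types == "TRA",
                     vapply(chrom1, function(c1)
                       sample(setdiff(g$chromosomes$name, c1), 1), ""), chrom1)
    pos1 <- sample.int(3e6, 400) + 1e5
    size <- round(10^runif(400, 0.5, 6.5))
    pos2 <- ifelse(types == "TRA", sample.int(3e6, 400) + 1e5, pos1 + size)
    df <- data.frame(sample_id = paste0("S", sample.int(5, 400, TRUE)),
                     caller = "x", chrom1 = chrom1, pos1 = pos1, strand1 = NA,
                     chrom2 = chrom2, pos2 = pos2, strand2 = NA, svtype = types,
                     split_reads = 1, read_pairs = 1, homology_len = NA,
                     insertion_len = NA)
    svs <- sv_calls(df, g)
    typed <- subtype_inversions_translocations(svs, cfg)
    sub <- classify_simple(typed, schema, g, cfg)
    expect_equal(length(sub), nrow(typed))
    expect_true(all(sub %in% schema$subcategory))
    # catalog row sums conserve the per-sample simple-SV count (pairs once)
    typed$subcategory <- sub
    cat <- build_catalog(typed, schema)
    expect_equal(unname(rowSums(cat)),
                 as.integer(table(typed$sample_id)[rownames(cat)]))
  })
})

test_that("the BRAF-fusion flag requires the size window and the configured region", {
  g <- toy_genome()  # BRAF region chr2:4e6-7e6
  cfg <- catalog_config()
  typed <- subtype_inversions_translocations(mk_calls(
    mk_call("chr2", 4.2e6, "chr2", 5.7e6, "DUP"),   # 1.5 Mb inside region
    mk_call("chr2", 4.2e6, "chr2", 7.2e6, "DUP"),   # 3 Mb: too large
    mk_call("chr1", 4.2e6, "chr1", 5.7e6, "DUP")),  # right size, wrong locus
    cfg)
  expect_equal(flag_braf_fusion(typed, g), c(TRUE, FALSE, FALSE))

  no_region <- genome_model(data.frame(name = "chr2", length = 8e6))
  expect_warning(fl <- flag_braf_fusion(typed[typed$chrom1 == "chr2", ], no_region),
                 "BRAF")
  expect_false(any(fl))
})

test_that("catalog construction counts one entry per simple SV", {
  schema <- simple_sv_schema()
  g <- toy_genome()
  cfg <- catalog_config()
  one <- subtype_inversions_translocations(
    mk_calls(mk_call("chr1", 5e6, "chr1", 5e6 + 900, "DEL")), cfg)
  one$subcategory <- classify_simple(one, schema, g, cfg)
  cat1 <- build_catalog(one, schema)
  expect_equal(dim(cat1), c(1, 49))
  expect_equal(sum(cat1), 1)
  expect_equal(sum(cat1[1, grep("^DEL_", colnames(cat1))]), 1)

  empty <- build_catalog(one[0, ], schema, sample_ids = character())
  expect_equal(dim(empty), c(0, 49))
})
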