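minimal_nexus <- "#NEXUS
BEGIN DATA;
  DIMENSIONS NTAX=2 NCHAR=1;
  FORMAT SYMBOLS=\"0~1\" MISSING=? GAP=-;
  MATRIX
  taxA 0
  taxB 1
  ;
END;
"

test_that("a minimal document parses in both dialects", {
  m <- parse_matrix(minimal_nexus, "nexus")
  expect_equal(n_taxa(m), 2)
  expect_equal(n_char(m), 1)
  expect_equal(m$state_domain[[1]], c(0L, 1L))
  expect_false(anyNA(m$cells))
  expect_equal(m$chars$kind, "binary")

  m2 <- parse_matrix(c("xread", "1 2", "taxA 0", "taxB 1", ";"), "tnt")
  expect_equal(m2$cells, m$cells)
  expect_equal(m2$taxa, m$taxa)
})

test_that("polymorphic and missing cell symbols parse correctly", {
  doc <- c("xread", "3 2", "a [01]?0", "b 2-1", ";")
  m <- parse_matrix(doc, "tnt")
  expect_equal(cell_states(m, "a", 1), c(0L, 1L))
  expect_true(is.na(cell_states(m, "a", 2)))   # ?
  expect_true(is.na(cell_states(m, "b", 2)))   # - (inapplicable)
  expect_equal(cell_states(m, "b", 1), 2L)

  nx <- sub("taxA 0", "taxA (01)", minimal_nexus)
  mnx <- parse_matrix(nx, "nexus")
  expect_equal(cell_states(mnx, "taxA", 1), c(0L, 1L))
  nx2 <- sub("taxA 0", "taxA {01}", minimal_nexus)
  expect_equal(cell_states(parse_matrix(nx2, "nexus"), "taxA", 1), c(0L, 1L))
})

test_that("structural errors are reported with the offending taxon", {
  expect_error(parse_matrix(c("xread", "2 2", "a 01", "b 0", ";"), "tnt"),
               "taxon 'b'")
  expect_error(parse_matrix(c("xread", "2 2", "a 01", "a 10", ";"), "tnt"),
               "duplicate")
  expect_error(parse_matrix(c("xread", "2 2", "a 0X", "b 01", ";"), "tnt"),
               "unknown symbol")
})

test_that("ordering declarations set character kinds", {
  doc <- c("xread", "3 4", "a 000", "b 111", "c 222", "d 012", ";",
           "ccode + 0;", "ccode - 1;")
  m <- parse_matrix(doc, "tnt")
  expect_equal(m$chars$kind, c("ordered", "unordered", "unordered"))
  # undeclared three-state character defaults to unordered, two-state to binary
  doc2 <- c("xread", "2 3", "a 00", "b 11", "c 21", ";")
  m2 <- parse_matrix(doc2, "tnt")
  expect_equal(m2$chars$kind, c("unordered", "binary"))
})

test_that("the bundled matrix passes its audit", {
  m <- load_moriomorphini()
  expect_equal(n_taxa(m), 22)
  expect_equal(n_char(m), 75)
  expect_equal(m$taxa[1], "Trechus obtusus")
  expect_equal(as.vector(table(m$chars$kind)[c("binary", "ordered", "unordered")]),
               c(33L, 30L, 12L))
  expect_equal(m$chars$kind[14], "unordered")  # mentum medial tooth
  expect_equal(m$chars$kind[16], "ordered")    # antennae
  expect_equal(m$chars$kind[4], "ordered")     # two-state but flagged additive

  # exactly three polymorphic terminals, where the table prints brackets
  dec <- moriomorph:::decode_mask
  npoly <- sum(vapply(m$cells, function(x)
    !is.na(x) && length(dec(x)) > 1, TRUE))
  expect_equal(npoly, 3)
  expect_equal(cell_states(m, "Trechus obtusus", 47), c(0L, 1L))
  expect_equal(cell_states(m, "Meonochilus eplicatus", 46), c(0L, 1L))
  expect_equal(cell_states(m, "Tropopterus duponcheli", 5), c(1L, 2L))

  # missing cells: the inapplicable subapical-region cell and the
  # sex-limited runs of the female-only/male-only terminals
  expect_true(is.na(cell_states(m, "Tropopterus duponcheli", 35)))
  ross <- which(is.na(m$cells[match("Rossjoycea glacialis", m$taxa), ]))
  expect_true(all(c(53, 54, 58:64) %in% ross))
  expect_equal(sum(is.na(m$cells)), 29)

  # every scored cell is inside its column's state domain
  for (j in seq_len(75)) {
    obs <- unlist(lapply(m$cells[, j], function(x)
      if (is.na(x)) NULL else dec(x)))
    expect_true(all(obs %in% m$state_domain[[j]]))
  }
})

test_that("write/parse round-trips are exact in both dialects", {
  m <- load_moriomorphini()
  for (d in c("nexus", "tnt")) {
    m2 <- parse_matrix(write_matrix(m, d), d)
    expect_identical(m2$cells, m$cells)
    expect_identical(m2$taxa, m$taxa)
    expect_identical(m2$chars$kind, m$chars$kind)
  }
  # simulated + degraded matrices round-trip too
  for (s in 1:3) {
    cfg <- sim_config(n_taxa = 8, n_characters = 20, states_per_character = 4,
                      fraction_ordered = 0.5, missing_rate = 0.2,
                      polymorphism_rate = 0.15, seed = s)
    sm <- degrade_matrix(simulate_characters(simulate_tree(cfg), cfg), cfg)
    for (d in c("nexus", "tnt")) {
      sm2 <- parse_matrix(write_matrix(sm, d), d)
      expect_identical(sm2$cells, sm$cells)
      expect_identical(sm2$chars$kind, sm$chars$kind)
    }
  }
})

test_that("written symbols follow the dialect conventions", {
  enc <- moriomorph:::encode_states
  cells <- matrix(c(enc(c(0L, 2L)), NA_integer_, enc(1L), enc(0L)), nrow = 2)
  m <- char_matrix(c("a", "b"), cells, c("unordered", "binary"))
  tnt <- write_matrix(m, "tnt")
  expect_match(tnt, "\\[02\\]")
  expect_match(tnt, "\\?")
  nx <- write_matrix(m, "nexus")
  expect_match(nx, "\\(02\\)")
  expect_match(nx, "\\?")
})
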