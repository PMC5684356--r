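# Glycan grammar, pathway fixture, rules, enumeration and distances.

test_that("glycan names parse, format and round-trip", {
  g0 <- parseGlycanName("G0")
  expect_equal(unlist(g0[, c("gal", "sia")]), c(gal = 0L, sia = 0L))
  expect_false(g0$fuc); expect_false(g0$bis)
  s <- parseGlycanName("G2FS1")
  expect_equal(s$gal, 2L); expect_true(s$fuc)
  expect_false(s$bis); expect_equal(s$sia, 1L)
  panel <- panelStructures(knownPathway())
  expect_identical(
    formatGlycanName(panel$gal, panel$fuc, panel$bis, panel$sia),
    panel$name)
  # re-parsing the formatted names reproduces the features
  rt <- parseGlycanName(panel$name)
  expect_identical(rt[, c("gal", "fuc", "bis", "sia")],
                   panel[, c("gal", "fuc", "bis", "sia")])
})

test_that("invalid glycan names are rejected with the violated invariant", {
  expect_error(parseGlycanName("G0S1"), "sialic acid")
  expect_error(parseGlycanName("G3"), "malformed")
  expect_error(parseGlycanName("G1NF"), "malformed")   # wrong token order
  expect_error(parseGlycanName("G2S3"), "malformed")
})

test_that("singleAddition identifies the enzyme of one-unit additions", {
  expect_identical(singleAddition("G1F", "G2F"), "B4GalT1")
  expect_identical(singleAddition("G1S1", "G2S1"), "B4GalT1")
  expect_identical(singleAddition("G0", "G0F"), "FUT8")
  expect_identical(singleAddition("G1", "G1N"), "MGAT3")
  expect_identical(singleAddition("G1", "G1S1"), "ST6Gal1")
  expect_identical(singleAddition("G0", "G0FN"), NA_character_) # two units
  expect_identical(singleAddition("G2F", "G1F"), NA_character_) # removal
  expect_identical(singleAddition("G0", "G0"), NA_character_)
})

test_that("the shipped pathway fixture is a valid single-addition graph", {
  kp <- knownPathway()
  panel <- panelStructures(kp)
  rx <- reactions(kp)
  expect_equal(nrow(panel), 22L)
  expect_equal(sum(panel$measured), 20L)
  expect_equal(nrow(rx), 21L)
  # validity already enforces the single-addition property; spot-check the
  # core fucosylation arrow
  expect_true(any(rx$substrate == "G0" & rx$product == "G0F" &
                  rx$enzyme == "FUT8"))
  # subclass panels: IgG4 carries only fucosylated structures
  panels <- subclassPanels(kp)
  expect_equal(lengths(panels)[c("IgG1", "IgG2", "IgG4")],
               c(IgG1 = 20L, IgG2 = 20L, IgG4 = 10L))
  igg4 <- parseGlycanName(panels$IgG4)
  expect_true(all(igg4$fuc))
})

test_that("pathway files with multi-unit edges fail validation", {
  def <- list(
    panel = list(list(name = "G0", measured = TRUE),
                 list(name = "G1", measured = TRUE),
                 list(name = "G2", measured = TRUE)),
    reactions = list(list("G0", "G2", "B4GalT1")))
  f <- tempfile(fileext = ".json")
  jsonlite::write_json(def, f, auto_unbox = TRUE)
  expect_error(loadPathway(f), "single matching addition")
})

test_that("candidate reactions match a brute-force double-loop oracle", {
  kp <- knownPathway()
  cand <- candidateReactions(kp)
  # independent O(n^2) oracle over ordered panel pairs
  panel <- panelStructures(kp)$name
  rx <- reactions(kp)
  oracle <- 0L
  oracleHasG0N <- FALSE
  for (a in panel) for (b in panel) {
    if (a == b) next
    enz <- singleAddition(a, b)
    if (is.na(enz)) next
    if (any(rx$substrate == a & rx$product == b)) next
    oracle <- oracle + 1L
    if (a == "G0N" && b == "G0FN") oracleHasG0N <- TRUE
  }
  expect_equal(nrow(cand), oracle)
  expect_equal(nrow(cand), 22L)
  expect_true(oracleHasG0N)
  # the in-vitro-inhibited fucosylation of G0N is deliberately a candidate
  expect_true(any(cand$substrate == "G0N" & cand$product == "G0FN" &
                  cand$enzyme == "FUT8"))
  # a saturated model has no candidates left
  full <- extendModel(kp, names(pathwayRules(kp)))
  expect_equal(nrow(candidateReactions(full)), 0L)
})

test_that("rules partition the candidate set", {
  kp <- knownPathway()
  mem <- lapply(names(pathwayRules(kp)), function(r) ruleMembers(kp, r))
  names(mem) <- names(pathwayRules(kp))
  sizes <- vapply(mem, nrow, 0L)
  expect_equal(sizes, c(F1 = 2L, F2 = 5L, F3 = 3L, G1 = 4L, N1 = 4L,
                        N2 = 4L))
  all <- do.call(rbind, mem)
  key <- paste(all$substrate, all$product)
  expect_equal(anyDuplicated(key), 0L)        # each reaction in one rule
  cand <- candidateReactions(kp)
  expect_setequal(key, paste(cand$substrate, cand$product))
})

test_that("extendModel adds rule reactions idempotently and monotonically", {
  kp <- knownPathway()
  expect_equal(reactions(extendModel(kp, character()))[, 1:3],
               reactions(kp)[, 1:3])
  ext <- extendModel(kp, c("G1", "N2"))
  expect_equal(nrow(reactions(ext)) - nrow(reactions(kp)), 8L)
  expect_equal(sort(ruleIds(ext)), c("G1", "N2"))
  # idempotent
  expect_equal(reactions(extendModel(ext, c("G1", "N2"))), reactions(ext))
  expect_error(extendModel(kp, "Z9"), "unknown rule")
  # N1 extension count equals the predicate-filter oracle over candidates
  cand <- candidateReactions(kp)
  sub <- parseGlycanName(cand$substrate)
  oracle <- sum(cand$enzyme == "MGAT3" & sub$gal >= 1 & !sub$fuc)
  expect_equal(nrow(reactions(extendModel(kp, "N1"))) - nrow(reactions(kp)),
               oracle)
  # candidates of the extended model no longer contain the rule members
  extCand <- candidateReactions(ext)
  memKey <- paste(rbind(ruleMembers(kp, "G1"), ruleMembers(kp, "N2"))$substrate,
                  rbind(ruleMembers(kp, "G1"), ruleMembers(kp, "N2"))$product)
  expect_length(intersect(paste(extCand$substrate, extCand$product), memKey),
                0L)
})

test_that("enumerateModels builds the rule power set", {
  kp <- knownPathway()
  models <- enumerateModels(kp)
  expect_length(models, 64L)
  expect_true("" %in% names(models))           # the known pathway itself
  expect_equal(anyDuplicated(names(models)), 0L)
  expect_length(enumerateModels(kp, character()), 1L)
  expect_length(enumerateModels(kp, c("G1", "N2")), 4L)
  # every enumerated model contains the known pathway
  knownKey <- paste(reactions(kp)$substrate, reactions(kp)$product)
  for (m in models)
    expect_true(all(knownKey %in%
                    paste(reactions(m)$substrate, reactions(m)$product)))
})

test_that("pathway distance equals a BFS oracle and behaves as a metric", {
  kp <- knownPathway()
  panel <- panelStructures(kp)$name
  expect_equal(pathwayDistance(kp, "G0", "G2S1"), 3)
  expect_equal(pathwayDistance(kp, "G0", "G0"), 0)
  # reactant/product pairs sit at distance 1
  rx <- reactions(kp)
  for (r in sample(nrow(rx), 5L))
    expect_equal(pathwayDistance(kp, rx$substrate[r], rx$product[r]), 1)
  expect_error(pathwayDistance(kp, "G0", "G2NS2"), "not in panel")
  dm <- distanceMatrix(kp)
  # full comparison against the independent BFS oracle
  for (a in panel) for (b in panel)
    expect_equal(dm[a, b], bfsDistance(rx, a, b, panel))
  # metric properties on the (connected) panel
  expect_equal(dm, t(dm))
  expect_true(all(diag(dm) == 0))
  expect_true(all(dm[upper.tri(dm)] > 0))
  for (k in panel)
    expect_true(all(dm <= outer(dm[, k], dm[k, ], `+`) + 1e-9))
})

test_that("rule extension never increases pathway distances", {
  kp <- knownPathway()
  dmKnown <- distanceMatrix(kp)
  for (m in enumerateModels(kp)) {
    dm <- distanceMatrix(m)[rownames(dmKnown), colnames(dmKnown)]
    expect_true(all(dm <= dmKnown + 1e-9))
  }
})
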