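test_that("the domain map partitions the 920-residue reference", {
  dom <- ar_domains()
  expect_equal(sum(dom$length), 920)
  assigned <- assign_domain(1:920)
  expect_equal(length(assigned), 920)
  expect_false(anyNA(assigned))
  # each residue falls in exactly one interval
  counts <- table(assigned)
  expect_equal(as.integer(counts[dom$domain]), dom$length)
})

test_that("positions map to the expected domains", {
  expect_equal(assign_domain(300), "NTD")
  expect_equal(assign_domain(600), "DBD")
  expect_equal(assign_domain(752), "LBD")
  expect_equal(assign_domain(559), "NTD") # NTD-DBD linker residue
  expect_equal(assign_domain(650), "hinge")
  expect_error(assign_domain(950), "out of range")
  expect_error(assign_domain(0), "out of range")
})

test_that("variant rows are validated with reasons, never silently dropped", {
  df <- tibble::tibble(
    position = c("738", "300", "950", "120", "45"),
    ref_aa = c("I", "Q", "A", "B", "C"),
    alt_aa = c("T", "Q", "V", "V", "*"),
    source = "HGMD",
    phenotype = c("PAIS", "", "", "", "CAIS")
  )
  cat <- validate_variants(df)
  rej <- rejected_variants(cat)
  expect_equal(nrow(cat) + nrow(rej), nrow(df))
  expect_equal(cat$position, c(738L, 45L))
  expect_equal(cat$mutation_class, c("missense", "nonsense"))
  expect_equal(cat$phenotype, c("PAIS", "CAIS"))
  expect_equal(cat$domain[1], "LBD")
  expect_setequal(rej$reason, c(
    "reference and alternate amino acids identical",
    "position out of range 1-920",
    "unknown reference amino acid"
  ))
})

test_that("parser accounting holds on randomized tables", {
  set.seed(11)
  for (i in 1:5) {
    n <- sample(20:60, 1)
    df <- tibble::tibble(
      position = as.character(sample(-50:1000, n, replace = TRUE)),
      ref_aa = sample(c("A", "R", "L", "B", "Z"), n, replace = TRUE),
      alt_aa = sample(c("V", "W", "A", "?", "fs"), n, replace = TRUE),
      source = "x", phenotype = ""
    )
    cat <- validate_variants(df)
    expect_equal(nrow(cat) + nrow(rejected_variants(cat)), n)
  }
})

test_that("a column map and coordinate offset are honoured", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("pos,from,to,db", "737,I,T,HGMD"), path)
  cat <- parse_variant_table(
    path,
    col_map = c(position = "pos", ref_aa = "from", alt_aa = "to",
                source = "db"),
    offset = 1L
  )
  expect_equal(cat$position, 738L)
  expect_equal(cat$source, "HGMD")
})

test_that("domain statistics count residues and variants correctly", {
  toy <- tibble::tibble(
    position = c(700L, 700L, 800L),
    ref_aa = c("A", "A", "L"),
    alt_aa = c("V", "G", "P")
  )
  st <- domain_stats(toy)
  lbd <- st[st$domain == "LBD", ]
  expect_equal(lbd$residues_mutated, 2L)
  expect_equal(lbd$variant_count, 3L)
  expect_equal(st$variant_count[st$domain != "LBD"], rep(0L, 3))
  expect_equal(sum(st$variant_count), nrow(toy))
  expect_true(all(st$fraction_mutated >= 0 & st$fraction_mutated <= 1))
})

test_that("constructed LBD coverage is reported back as the same fraction", {
  # cover 129 of the 230 LBD residues (~56%), one variant each
  positions <- 691L + seq_len(129) - 1L
  cat <- tibble::tibble(position = positions, ref_aa = "A", alt_aa = "V")
  st <- domain_stats(cat)
  expect_equal(st$fraction_mutated[st$domain == "LBD"], 0.56,
    tolerance = 0.01
  )
})

test_that("three-way overlap counts enumerate the 7 Venn regions", {
  mk <- function(pos) {
    tibble::tibble(position = pos, ref_aa = "A", alt_aa = "V")
  }
  same <- list(A = mk(1:5), B = mk(1:5), C = mk(1:5))
  v <- dataset_overlap(same)
  expect_equal(v$n[v$region == "A & B & C"], 5L)
  expect_equal(sum(v$n), 5L)

  disjoint <- list(A = mk(1:3), B = mk(4:5), C = mk(6))
  v <- dataset_overlap(disjoint)
  expect_equal(v$n[v$region == "A"], 3L)
  expect_equal(v$n[v$region == "B"], 2L)
  expect_equal(v$n[v$region == "C"], 1L)
  expect_equal(sum(v$n), 6L)

  # A = {x, y}, B = {y, z}, C = {z}
  abc <- list(A = mk(c(1, 2)), B = mk(c(2, 3)), C = mk(3))
  v <- dataset_overlap(abc)
  expect_equal(v$n[v$region == "A & B"], 1L)
  expect_equal(v$n[v$region == "B & C"], 1L)
  expect_equal(v$n[v$region == "A"], 1L)
  expect_equal(v$n[v$region == "A & B & C"], 0L)
})

test_that("Venn region counts always sum to the union size", {
  set.seed(3)
  for (i in 1:10) {
    mk <- function() {
      tibble::tibble(
        position = sample(1:60, sample(5:30, 1), replace = TRUE),
        ref_aa = "A", alt_aa = "V"
      )
    }
    sets <- list(X = mk(), Y = mk(), Z = mk())
    keys <- unique(unlist(lapply(sets, function(s) {
      paste(s$position, s$ref_aa, s$alt_aa)
    })))
    expect_equal(sum(dataset_overlap(sets)$n), length(keys))
  }
})

test_that("free-text phenotype annotations normalise to the vocabulary", {
  expect_equal(classify_phenotype("CAIS"), "CAIS")
  expect_equal(classify_phenotype("partial androgen insensitivity"), "PAIS")
  expect_equal(classify_phenotype("complete AIS"), "CAIS")
  expect_equal(classify_phenotype("mild AIS"), "MAIS")
  expect_equal(classify_phenotype("prostate cancer"), "prostate_cancer")
  expect_equal(classify_phenotype("premature ovarian failure"), "POF")
  expect_equal(classify_phenotype(""), "unknown")
  expect_equal(classify_phenotype("??"), "unknown")
  expect_equal(
    classify_phenotype("spinal", synonyms = c("spinal" = "none")),
    "none"
  )
})
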