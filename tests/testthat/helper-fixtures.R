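# Fixtures are generated in code and memoised for the whole test run; every
# generator is seeded, so the suite is fully deterministic.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# Small one-mismatch nuMT fixture (3 kb mito, focal at centre, flank 150).
small_fixture <- function() {
  cached("small_fixture", {
    fx <- one_mismatch_fixture(seed = 11, mito_length = 3000, flank = 150)
    fx$index <- build_index(fx$refset)
    fx
  })
}

# Plain mitochondrial genome with no nuclear contigs (unconfounded world).
plain_refset <- function() {
  cached("plain_refset", {
    rs <- reference_set(make_mito_genome(2000, seed = 5))
    list(refset = rs, index = build_index(rs))
  })
}

# Two-mismatch fixture for the haplotype background scan.
hap_fixture <- function() {
  cached("hap_fixture", {
    fx <- two_mismatch_fixture(seed = 2)
    fx$index <- build_index(fx$refset)
    fx
  })
}

se100 <- function() read_config(100L)

expect_same_alignment <- function(a, b) {
  expect_equal(a$mapped, b$mapped)
  expect_equal(a$contig, b$contig)
  expect_equal(a$pos, b$pos)
  expect_equal(a$strand, b$strand)
  expect_equal(a$mismatches, b$mismatches)
  expect_equal(a$ambiguous, b$ambiguous)
}

# Deterministic local RNG for test-generated reads.
with_test_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

random_read <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                                 collapse = "")

mutate_read <- function(read, n_mut) {
  pos <- sample(nchar(read), n_mut)
  for (p in pos) {
    cur <- substr(read, p, p)
    substr(read, p, p) <- sample(setdiff(c("A", "C", "G", "T"), cur), 1)
  }
  read
}
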