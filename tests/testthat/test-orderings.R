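test_that("descending ordering ranks by population with stable tu_id tie-break", {
  pops <- tibble::tibble(tu_id = c("TU1", "TU2", "TU3"), population = c(10, 50, 20))
  ord <- make_ordering(pops, "descending")
  expect_equal(ord$tu_id, c("TU2", "TU3", "TU1"))
  expect_equal(ord$index, 1:3)
  # ties broken by ascending tu_id
  ties <- tibble::tibble(tu_id = c("b", "a", "c"), population = c(5, 5, 5))
  expect_equal(make_ordering(ties, "descending")$tu_id, c("a", "b", "c"))
})

test_that("bell ordering centers the largest unit and decreases toward both ends", {
  pops <- tibble::tibble(tu_id = c("TU1", "TU2", "TU3"), population = c(10, 50, 20))
  ord <- make_ordering(pops, "bell")
  expect_equal(ord$tu_id[ord$index == 2], "TU2")  # largest at the center
  for (n in c(4, 5, 8, 33)) {
    pops <- withr::with_seed(n, tibble::tibble(
      tu_id = sprintf("TU%02d", 1:n),
      population = sample(seq(1e4, 1e6, length.out = n))
    ))
    ord <- make_ordering(pops, "bell")
    b <- pops$population[match(ord$tu_id, pops$tu_id)]  # by index
    peak <- which.max(b)
    expect_equal(peak, floor(n / 2) + 1)
    expect_true(all(diff(b[seq_len(peak)]) > 0))        # rising to the center
    expect_true(all(diff(b[peak:n]) < 0))               # falling after it
  }
})

test_that("orderings are idempotent under relabelling by index", {
  pops <- tibble::tibble(tu_id = sprintf("TU%02d", 1:9),
                         population = c(3, 9, 1, 7, 5, 8, 2, 6, 4) * 1e5)
  for (scheme in c("descending", "bell", "original")) {
    ord1 <- make_ordering(pops, scheme)
    relabelled <- tibble::tibble(
      tu_id = sprintf("I%02d", ord1$index),
      population = pops$population[match(ord1$tu_id, pops$tu_id)]
    )
    ord2 <- make_ordering(relabelled, scheme)
    expect_equal(ord2$index, match(ord2$tu_id, relabelled$tu_id))
    expect_equal(ord2$tu_id, relabelled$tu_id)
  }
})

test_that("duplicate units and multi-year input without a reference year are rejected", {
  dup <- tibble::tibble(tu_id = c("a", "a"), population = c(1, 2))
  expect_error(make_ordering(dup, "descending"), "duplicate")
  panel <- random_panel(n = 4, years = 2000:2001, seed = 3)
  expect_error(make_ordering(panel, "descending"), "reference_year")
  ord <- make_ordering(panel, "descending", reference_year = 2001)
  expect_equal(attr(ord, "reference_year"), 2001)
})

test_that("orderings round-trip through CSV", {
  pops <- tibble::tibble(tu_id = sprintf("TU%02d", 1:6),
                         population = c(4, 1, 6, 3, 5, 2) * 1e4)
  ord <- make_ordering(pops, "bell")
  path <- withr::local_tempfile(fileext = ".csv")
  write_ordering(ord, path)
  ord2 <- read_ordering(path)
  expect_equal(ord2$tu_id, ord$tu_id)
  expect_equal(ord2$index, ord$index)
})
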