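
test_that("a single horizontal strand is counted once on every grid line", {
  net <- strand_network(list(list(id = 1, appearance = "particle",
                                  segments = list(cbind(seq(0, 2000, 50), 0)))),
                        apical_id = 1)
  sc <- strand_counts(net)
  expect_true(all(sc$per_line$count == 1L))
  expect_equal(sc$mean_strand_number, 1)
  expect_equal(meshwork_depth(net), 0)
})

test_that("parallel generator strands give exact counts and depth", {
  gen <- make_strand_network(4, depth_nm = 300, seed = 9)
  sc <- strand_counts(gen$network)
  expect_equal(sc$mean_strand_number, 4)
  expect_equal(meshwork_depth(gen$network), 300, tolerance = 5 / 300)
  expect_equal(sc$per_line$count, oracle_counts(gen$network, sc$grid))

  # two coincident strands have zero depth
  seg <- cbind(seq(0, 1000, 25), 50)
  twin <- strand_network(list(
    list(id = 1, appearance = "particle", segments = list(seg)),
    list(id = 2, appearance = "particle", segments = list(seg))),
    apical_id = 1)
  expect_equal(meshwork_depth(twin), 0)
})

test_that("a strand ending halfway is counted only where it exists", {
  full <- function(id, y) list(id = id, appearance = "particle",
                               segments = list(cbind(seq(0, 2000, 25), y)))
  half <- list(id = 4, appearance = "particle",
               segments = list(cbind(seq(0, 1000, 25), 300)))
  net <- strand_network(list(full(1, 0), full(2, 100), full(3, 200), half),
                        apical_id = 1)
  sc <- strand_counts(net)
  expect_gt(sc$mean_strand_number, 3)
  expect_lt(sc$mean_strand_number, 4)
  expect_equal(sc$per_line$count, oracle_counts(net, sc$grid))
})

test_that("breaks are gaps strictly greater than the threshold", {
  cont <- make_strand_network(3, seed = 2)
  expect_equal(detect_breaks(cont$network), 0L)

  gen <- make_strand_network(4, depth_nm = 300,
                             breaks = tibble::tibble(strand = c(2, 3, 4),
                                                     gap_nm = 30), seed = 7)
  expect_equal(detect_breaks(gen$network), 3L)

  # an exactly-20 nm gap is not a break
  exact <- strand_network(list(list(
    id = 1, appearance = "particle",
    segments = list(cbind(c(0, 100), c(0, 0)), cbind(c(120, 220), c(0, 0))))),
    apical_id = 1)
  expect_equal(detect_breaks(exact), 0L)
  expect_equal(detect_breaks(exact, min_gap = 19.999), 1L)
})

test_that("appearance proportions are exact fractions with labelled input", {
  gen <- make_strand_network(4, appearance = c("particle", "particle",
                                               "particle", "continuous"),
                             seed = 1)
  props <- appearance_proportions(gen$network)
  expect_equal(props$proportion_particle, 0.75)
  expect_equal(props$proportion_continuous, 0.25)
  expect_equal(props$proportion_particle + props$proportion_continuous, 1)

  allp <- make_strand_network(3, seed = 1)
  expect_equal(appearance_proportions(allp$network)$proportion_particle, 1)

  bad <- allp$network
  bad$strands[[2]]$appearance <- ""
  expect_error(appearance_proportions(bad), "labelled")
})

test_that("morphometry is invariant under rigid rotation and translation", {
  gen <- make_strand_network(4, depth_nm = 300,
                             breaks = tibble::tibble(strand = 2, gap_nm = 40),
                             seed = 5)
  base <- strand_morphometry(gen$network)
  th <- 0.6; R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  shift <- c(500, -200)
  moved <- gen$network
  moved$strands <- lapply(moved$strands, function(st) {
    st$segments <- lapply(st$segments, function(seg) {
      sweep(seg %*% t(R), 2, -shift)
    })
    st
  })
  got <- strand_morphometry(moved)
  expect_equal(got$mean_strand_number, base$mean_strand_number)
  expect_equal(got$depth_nm, base$depth_nm, tolerance = 1e-6)
  expect_equal(got$n_breaks, base$n_breaks)
})

test_that("adding a strand above the apical one cannot reduce the mean count", {
  gen <- make_strand_network(3, depth_nm = 200, seed = 3)
  base <- strand_counts(gen$network)$mean_strand_number
  above <- list(id = 99, appearance = "particle",
                segments = list(cbind(seq(0, 2400, 25), -80)))
  bigger <- strand_network(c(gen$network$strands, list(above)), apical_id = 99)
  expect_gte(strand_counts(bigger)$mean_strand_number, base)
})

test_that("strand annotations round-trip through JSON", {
  gen <- make_strand_network(3, depth_nm = 150,
                             breaks = tibble::tibble(strand = 2, gap_nm = 30),
                             seed = 6)
  tmp <- tempfile(fileext = ".json")
  write_strand_json(gen$network, tmp)
  back <- read_strand_json(tmp)
  expect_equal(back$apical_id, gen$network$apical_id)
  expect_equal(length(back$strands), 3L)
  expect_equal(back$strands[[2]]$segments[[1]],
               gen$network$strands[[2]]$segments[[1]], tolerance = 1e-12)
  expect_equal(strand_morphometry(back), strand_morphometry(gen$network))
})
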