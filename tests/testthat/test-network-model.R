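# Data model, file I/O and summary statistics of vascular networks.

simple_net <- function() {
  vascular_network(
    data.frame(id = c(10, 20), x = c(0, 100), y = 0, z = 0),
    data.frame(id = 5, from = 10, to = 20, diameter = 10, length = 100)
  )
}

test_that("the smallest valid graph has two boundary nodes and no interior", {
  net <- simple_net()
  expect_equal(nrow(net$nodes), 2L)
  expect_equal(sort(boundary_nodes(net)), 1:2)
  expect_length(interior_nodes(net), 0L)
  expect_equal(net$nodes$orig_id, c(10, 20))  # ids remapped, originals kept
})

test_that("structural validation rejects broken networks", {
  nodes <- data.frame(id = 1:2, x = c(0, 100), y = 0, z = 0)
  expect_error(
    vascular_network(nodes, data.frame(id = 1, from = 1, to = 3,
                                       diameter = 10, length = 100)),
    "absent from the node table"
  )
  expect_error(
    vascular_network(nodes, data.frame(id = 1, from = 1, to = 2,
                                       diameter = -1, length = 100)),
    "diameters"
  )
  # centreline length may exceed the chord but never undercut it
  expect_error(
    vascular_network(nodes, data.frame(id = 1, from = 1, to = 2,
                                       diameter = 10, length = 50)),
    "centreline"
  )
  expect_silent(
    vascular_network(nodes, data.frame(id = 1, from = 1, to = 2,
                                       diameter = 10, length = 150))
  )
})

test_that("csv and json round trips are the identity, and dialects agree", {
  net <- make_fixture(synthetic_spec("tumour_like", extent_um = 900, seed = 4))
  d_csv <- withr::local_tempdir()
  f_json <- withr::local_tempfile(fileext = ".json")
  write_network(net, d_csv, "csv")
  write_network(net, f_json, "json")
  back_csv <- read_network(d_csv, "csv")
  back_json <- read_network(f_json, "json")
  expect_equal(back_csv$nodes, net$nodes)
  expect_equal(back_csv$segments, net$segments)
  expect_equal(back_json, back_csv)
})

test_that("reading malformed or missing files fails with a named location", {
  expect_error(read_network(tempfile(), "csv"), "not found")
  bad <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(units = "um"), bad)
  expect_error(read_network(bad, "json"), "malformed")
  expect_error(write_network(
    structure(list(nodes = tibble::tibble(), segments = tibble::tibble()),
              class = "vascular_network"),
    tempfile()), "empty")
})

test_that("cleaning merges duplicates, reports components, and fixes clean nets", {
  # duplicate node at identical coordinates
  net <- vascular_network(
    data.frame(id = 1:4, x = c(0, 100, 100, 200), y = 0, z = 0),
    data.frame(id = 1:2, from = c(1, 3), to = c(2, 4), diameter = 10, length = 100),
    validate = TRUE
  )
  out <- validate_and_clean(net)
  expect_equal(out$report$count[out$report$action == "merged_duplicate_nodes"], 1L)
  expect_equal(nrow(out$network$nodes), 3L)
  expect_equal(attr(out$report, "n_components"), 1L)

  # two disconnected components; keep_largest retains the larger
  net2 <- vascular_network(
    data.frame(id = 1:5, x = c(0, 100, 200, 1000, 1100), y = 0, z = 0),
    data.frame(id = 1:3, from = c(1, 2, 4), to = c(2, 3, 5),
               diameter = 10, length = 100)
  )
  out2 <- validate_and_clean(net2)
  expect_equal(attr(out2$report, "n_components"), 2L)
  out2b <- validate_and_clean(net2, policy = "keep_largest")
  expect_equal(nrow(out2b$network$segments), 2L)

  # an already-clean lattice is a fixed point with an empty report
  lat <- make_fixture(synthetic_spec("lattice3d", k = 3))
  out3 <- validate_and_clean(lat)
  expect_identical(out3$network, lat)
  expect_equal(nrow(out3$report), 0L)
  expect_error(validate_and_clean(vascular_network(
    data.frame(id = 1:2, x = c(0, 100), y = 0, z = 0),
    data.frame(id = 1, from = 1, to = 2, diameter = 10, length = 100),
    validate = FALSE
  ) |> (\(n) { n$segments$length <- 0; n })()), "empty after cleaning")
})

test_that("network statistics match cylinder closed forms", {
  net <- simple_net()  # d = 10 um, l = 100 um
  st <- network_statistics(net, hull_volume_cm3 = 1e6 * 1e-12)  # 1e6 um3
  expect_equal(st$vessel_volume_cm3, 2500 * pi * 1e-12)
  expect_equal(st$vascular_density_pct, 100 * 2500 * pi / 1e6)
  expect_equal(st$surface_area_cm2, 1000 * pi * 1e-8)
  # S/V: 1000 pi um^2 / 1e6 um^3 = 1e-3 pi um^-1 = 10 pi cm^-1
  expect_equal(st$surface_to_volume_cm, 1000 * pi * 1e-8 / 1e-12 / 1e6)
  expect_equal(st$surface_to_volume_cm, 10 * pi)
})

test_that("chains of degree-2 nodes merge into one branching vessel", {
  net <- vascular_network(
    data.frame(id = 1:4, x = c(0, 100, 200, 300), y = 0, z = 0),
    data.frame(id = 1:3, from = 1:3, to = 2:4, diameter = 10, length = 100)
  )
  br <- network_branches(net)
  expect_equal(nrow(br), 1L)
  expect_equal(br$length, 300)
  expect_equal(br$n_segments, 3L)
  st <- network_statistics(net, 1e-6)
  expect_equal(st$mean_branch_length_um, 300)
})

test_that("branch decomposition covers every segment exactly once", {
  net <- fx_tumour()$net
  br <- network_branches(net)
  expect_equal(sum(br$n_segments), nrow(net$segments))
})

test_that("statistics are invariant to node re-indexing and translation", {
  net <- make_fixture(synthetic_spec("tumour_like", extent_um = 900, seed = 4))
  st0 <- network_statistics(net, 1e-4)
  # translate
  net_t <- net
  net_t$nodes$x <- net_t$nodes$x + 500
  net_t$nodes$z <- net_t$nodes$z - 200
  expect_equal(network_statistics(net_t, 1e-4), st0, tolerance = 1e-12)
  # permute node order
  set.seed(1)
  perm <- sample(nrow(net$nodes))
  inv <- match(seq_along(perm), perm)
  net_p <- vascular_network(
    data.frame(id = seq_along(perm), x = net$nodes$x[perm],
               y = net$nodes$y[perm], z = net$nodes$z[perm]),
    data.frame(id = net$segments$id, from = inv[net$segments$from],
               to = inv[net$segments$to],
               diameter = net$segments$diameter, length = net$segments$length)
  )
  st_p <- network_statistics(net_p, 1e-4)
  expect_equal(st_p$mean_branch_length_um, st0$mean_branch_length_um)
  expect_equal(st_p$vessel_volume_cm3, st0$vessel_volume_cm3)
  expect_equal(st_p$n_boundary_nodes, st0$n_boundary_nodes)
})
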