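test_that("topology files parse with genes in first-appearance order", {
  p <- write_topo_lines(c("Source Target Type", "A B 2", "B A 2"))
  ts <- read_topology(p)
  expect_identical(ts$genes, c("A", "B"))
  expect_equal(n_edges(ts), 2)
  expect_true(all(ts$edges$type == 2L))

  # self-activation listed first, header absent
  p2 <- write_topo_lines(c("A A 1", "A B 2", "B A 2"))
  sa <- read_topology(p2)
  expect_equal(n_genes(sa), 2)
  expect_equal(n_edges(sa), 3)
  expect_identical(sa$edges$type, c(1L, 2L, 2L))
})

test_that("malformed topology files are rejected with clear errors", {
  expect_error(read_topology(write_topo_lines(c("Source Target Type",
                                                "A B 3"))),
               "interaction type")
  expect_error(read_topology(write_topo_lines("Source Target Type")),
               "no edge rows")
  expect_error(read_topology(write_topo_lines(c("A B 2", "A B 2"))),
               "duplicate edge")
  expect_error(read_topology(write_topo_lines(c("A B"))), ".")
  expect_error(read_topology(tempfile()), "not found")
})

test_that("circuit constructor enforces its invariants", {
  e <- data.frame(source = "A", target = "B", type = 2)
  expect_error(circuit(character(0), e), "at least one gene")
  expect_error(circuit(c("A", "B"), e[0, ]), "at least one edge")
  expect_error(circuit("A", e), "not in gene list")
  expect_error(circuit(c("A", "B"), rbind(e, e)), "duplicate")
  expect_error(circuit(c("A", "B"),
                       data.frame(source = "A", target = "B", type = 5)),
               "unknown interaction type")
  expect_error(circuit(c("A", "A"), e), "duplicate gene")
})

test_that("fixture circuits have the expected gene and edge structure", {
  ts <- fixture_circuit("TS")
  expect_equal(c(n_genes(ts), n_edges(ts)), c(2, 2))
  expect_true(all(ts$edges$type == 2L))

  sa2 <- fixture_circuit("TS_SA2")
  expect_equal(n_edges(sa2), 4)
  self <- sa2$edges$source == sa2$edges$target
  expect_equal(sum(self), 2)
  expect_true(all(sa2$edges$type[self] == 1L))

  expect_equal(n_edges(fixture_circuit("TS_SA1")), 3)

  five <- fixture_circuit("FIVE_TS")
  expect_equal(n_genes(five), 10)
  expect_equal(n_edges(five), 15)  # 5 switch pairs + 5 ring couplings
  expect_error(fixture_circuit("NOPE"))
})

test_that("write/read round trip is the identity on every fixture", {
  for (nm in fixture_circuit_names()) {
    cir <- fixture_circuit(nm)
    path <- tempfile(fileext = ".tpo")
    write_topology(cir, path)
    back <- read_topology(path, name = cir$name)
    expect_identical(back, cir, label = nm)
  }
})

test_that("writing a circuit with edge-less genes warns about data loss", {
  cir <- circuit(c("A", "B", "C"),
                 data.frame(source = c("A", "B"), target = c("B", "A"),
                            type = 2L))
  expect_warning(write_topology(cir, tempfile()), "without edges")
})
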