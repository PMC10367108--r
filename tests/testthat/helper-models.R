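# Shared fixtures, built once per test run. Everything is generated in code;
# the default-resolution ventricle takes a couple of seconds and is reused by
# most files.

.fixtures <- new.env()

fixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
  .fixtures[[name]]
}

test_mesh <- function() fixture("mesh", function() generate_biventricular_mesh())
test_fibers <- function() fixture("fibers", function() assign_fibers(test_mesh()))
test_parc <- function() fixture("parc", function() parcellate_aha(test_mesh()))
test_labels <- function() fixture("labels", function() {
  label_tissue(test_mesh(), test_parc())
})
test_tree <- function() fixture("tree", function() {
  generate_purkinje_tree(test_mesh(), seed = 1L)
})
test_lbbb <- function() fixture("lbbb", function() {
  simulate_lbbb(test_mesh(), test_fibers(), conduction_model(), test_tree())
})
test_lbbb_ecg <- function() fixture("lbbb_ecg", function() {
  compute_ecg(test_mesh(), test_lbbb())
})

# a uniform-fiber slab along x, reused by the solver tests
test_slab <- function() fixture("slab", function() generate_slab_mesh(40, 10, 10, h = 2))
slab_fibers <- function(mesh, dir = c(1, 0, 0)) {
  matrix(rep(dir, each = nrow(mesh$tets)), ncol = 3)
}

# "degenerate" mesh whose element time equals a prescribed nodal value:
# every tet repeats one node, so constructed activation vectors map straight
# onto element times; used to test the feature formulas against closed forms
point_mesh <- function(times, volumes = rep(1, length(times)),
                       ventricle = rep("lv", length(times))) {
  n <- length(times)
  structure(list(
    nodes = cbind(seq_len(n), 0, 0),
    tets = cbind(seq_len(n), seq_len(n), seq_len(n), seq_len(n)),
    volumes = volumes,
    ventricle = ventricle,
    region = rep("lv_shell", n),
    surfaces = list(lv_epi = seq_len(n))
  ), class = "biv_mesh")
}

expect_no_na <- function(x) expect_false(anyNA(x))
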