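# Small in-code fixtures shared across test files.

# Poisson cell population: G genes x n cells, one individual / cell type.
make_poisson_cells <- function(G = 50, n = 30, lambda = 5, seed = 1,
                               individual = "ind1", cell_type = "Exc") {
  set.seed(seed)
  m <- matrix(rpois(G * n, lambda), G, n,
              dimnames = list(sprintf("g%03d", seq_len(G)),
                              sprintf("c%03d", seq_len(n))))
  list(counts = count_matrix(m),
       ann = cell_annotation(data.frame(
         cell_id = colnames(m), individual_id = individual,
         cell_type = cell_type, stringsAsFactors = FALSE)))
}

# Tiny deterministic 3-gene x 2-cell matrix from the worked examples.
tiny_counts <- function() {
  m <- matrix(c(0, 1, 2, 0, 5, 5), nrow = 3, byrow = TRUE,
              dimnames = list(c("g1", "g2", "g3"), c("c1", "c2")))
  count_matrix(m)
}

tiny_ann <- function(ids = c("c1", "c2"), individual = "ind1",
                     types = c("Exc", "Oli")) {
  cell_annotation(data.frame(cell_id = ids, individual_id = individual,
                             cell_type = types[seq_along(ids)],
                             stringsAsFactors = FALSE))
}

# Multi-individual / multi-type random population for grouping tests.
make_population <- function(G = 40, n_cells = 60, seed = 3) {
  set.seed(seed)
  m <- matrix(rpois(G * n_cells, 3), G, n_cells,
              dimnames = list(sprintf("g%03d", seq_len(G)),
                              sprintf("c%03d", seq_len(n_cells))))
  ann <- cell_annotation(data.frame(
    cell_id = colnames(m),
    individual_id = sample(c("i1", "i2", "i3"), n_cells, replace = TRUE),
    cell_type = sample(c("Exc", "Oli"), n_cells, replace = TRUE),
    stringsAsFactors = FALSE))
  list(counts = count_matrix(m), ann = ann)
}

# Paired-expression object built directly from two aligned matrices.
make_paired <- function(x, y) {
  dimnames(x) <- dimnames(y) <- list(sprintf("g%04d", seq_len(nrow(x))),
                                     sprintf("s%d", seq_len(ncol(x))))
  structure(list(genes = rownames(x), x_bulk = x, y_sc = y,
                 sample_ids = colnames(x)),
            class = "paired_expression")
}

# NB pseudo-bulk matrix with a two-group design.
make_nb_pseudobulk <- function(G = 500, n_per_group = 3, phi = 0.1,
                               fold = 1, frac_de = 0, seed = 1,
                               mu_range = c(20, 2000)) {
  set.seed(seed)
  mu <- exp(runif(G, log(mu_range[1]), log(mu_range[2])))
  n <- 2 * n_per_group
  shift <- rep(1, G)
  if (frac_de > 0) {
    n_de <- round(frac_de * G)
    up <- seq_len(ceiling(n_de / 2))
    dn <- seq.int(ceiling(n_de / 2) + 1, n_de)
    shift[up] <- fold
    shift[dn] <- 1 / fold
  }
  mu_mat <- cbind(matrix(mu, G, n_per_group),
                  matrix(mu * shift, G, n_per_group))
  draw <- function(m) {
    if (phi > 0) rnbinom(length(m), mu = m, size = 1 / phi)
    else rpois(length(m), m)
  }
  y <- matrix(draw(mu_mat), G, n)
  rownames(y) <- sprintf("g%04d", seq_len(G))
  colnames(y) <- sprintf("s%d", seq_len(n))
  list(y = y, group = rep(c("a", "b"), each = n_per_group),
       de_genes = if (frac_de > 0) rownames(y)[seq_len(round(frac_de * G))]
                  else character(0))
}
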