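# shared fixtures, built in code at test time

# tiny protein matrix with explicit values
small_pm <- function(log2 = TRUE) {
  vals <- matrix(c(10, 11, 12, 13,
                   NA, 11.5, 12.5, 13.5,
                   9, NA, 11, 12), nrow = 3, byrow = TRUE,
                 dimnames = list(c("PGa", "PGb", "PGc"),
                                 c("f1", "f2", "f3", "f4")))
  ann <- data.frame(fibre_id = c("f1", "f2", "f3", "f4"),
                    participant = c("P1", "P1", "P2", "P2"),
                    condition = "control")
  protein_matrix(vals, ann, log2 = log2)
}

# write a 3-protein x 2-run PG-matrix TSV + annotation CSV; returns the paths
write_pg_fixture <- function(dir = NULL, duplicate_id = FALSE,
                             extra_run = FALSE) {
  if (is.null(dir)) {
    dir <- tempfile("pgfx")
    dir.create(dir)
  }
  ids <- c("PG1", "PG2", if (duplicate_id) "PG1" else "PG3")
  pg <- data.frame(Protein.Group = ids,
                   Genes = c("MYH7", "MYH2", "ACTA1"),
                   run1 = c(100.25, 200.5, 400.125),
                   run2 = c(150.75, NA, 800.0625),
                   check.names = FALSE)
  if (extra_run) pg$run3 <- c(1, 2, 3)
  pg_path <- file.path(dir, "pg.tsv")
  write.table(pg, pg_path, sep = "\t", quote = FALSE, row.names = FALSE)
  ann <- data.frame(fibre_id = c("run1", "run2"),
                    participant = c("P1", "P2"), condition = "control")
  ann_path <- file.path(dir, "annot.csv")
  write.csv(ann, ann_path, row.names = FALSE, quote = FALSE)
  list(pg = pg_path, annot = ann_path)
}

# cohort annotations turned into a named fibre -> group vector
grouping_from_truth <- function(cohort, map = c(I = "typeI", IIa = "typeIIa")) {
  g <- map[cohort$fibre_truth$subtype]
  stats::setNames(unname(g), cohort$fibre_truth$fibre_id)
}

# lexicographic permutation enumeration, independent of the package's
# recursive builder (used as the exact-p oracle)
next_perm <- function(p) {
  n <- length(p)
  i <- n - 1L
  while (i >= 1L && p[i] >= p[i + 1L]) i <- i - 1L
  if (i < 1L) return(NULL)
  j <- n
  while (p[j] <= p[i]) j <- j - 1L
  tmp <- p[i]; p[i] <- p[j]; p[j] <- tmp
  p[(i + 1L):n] <- rev(p[(i + 1L):n])
  p
}

spearman_oracle <- function(x, y) {
  n <- length(x)
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  p <- sort(seq_len(n))
  count <- 0L; total <- 0L
  repeat {
    total <- total + 1L
    if (abs(stats::cor(rx, ry[p])) >= abs(rho) - 1e-12) count <- count + 1L
    p <- next_perm(p)
    if (is.null(p)) break
  }
  list(rho = rho, p = count / total)
}
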