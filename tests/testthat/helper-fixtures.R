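# shared fixtures and independent oracles, built once per test run

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- builder()
  .fixtures[[key]]
}

fix_spec <- function() bill_spec(base_width = 0.016, base_depth = 0.020,
                                 species_label = "default")

# coarse default bill mesh shared by several tests
fix_bill_mesh <- function() memo("bill_mesh", function()
  make_bill_mesh(fix_spec(), n_axial = 12, n_circumferential = 8))

# the full test-tier pipeline report, shared by the acceptance blocks
fix_report <- function() memo("report", function()
  suppressMessages(run_full_analysis(default_config(tier = "test", seed = 1))))

star_tree <- function(n, h = 1) {
  read_newick(text = paste0("(", paste(sprintf("t%d:%g", seq_len(n), h),
                                       collapse = ","), ");"))
}

# all permutations of 1..n (n small), one per row
all_perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    rest <- setdiff(seq_len(n), k)
    cbind(k, matrix(rest[sub], nrow(sub), n - 1L))
  }))
}

# brute-force two-sided permutation p-value for Spearman's rho
spearman_perm_p <- function(x, y) {
  n <- length(x)
  r_obs <- stats::cor(rank(x), rank(y))
  ry <- rank(y)
  perms <- all_perms(n)
  r_all <- apply(perms, 1, function(p) stats::cor(p, ry))
  mean(abs(r_all) >= abs(r_obs) - 1e-12)
}

# brute-force two-sided exact p for the Wilcoxon signed-rank statistic
wilcoxon_enum_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.vector(signs %*% r)
  mu <- n * (n + 1) / 4
  min(1, 2 * min(mean(w_all >= w_obs), mean(w_all <= w_obs)))
}

# 3x3 rotation matrix about the z axis
rot_z <- function(angle) {
  matrix(c(cos(angle), sin(angle), 0,
           -sin(angle), cos(angle), 0,
           0, 0, 1), 3, 3)
}
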