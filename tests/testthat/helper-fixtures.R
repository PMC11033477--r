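# shared fixtures, all built in code

# the hand-worked 3-gene x 4-sample table: A and B track each other
# exactly (constant 2-cycle offset), C wobbles around them
abc_table <- function() {
  m <- rbind(A = c(20.0, 20.1, 19.9, 20.0),
             B = c(22.0, 22.1, 21.9, 22.0),
             C = c(25.0, 25.5, 24.5, 25.0))
  colnames(m) <- paste0("s", 1:4)
  ct_table(m, groups = rep("g1", 4))
}

# random valid Ct table; per-sample loading + iid gene noise
random_table <- function(n_genes = 5, n_samples = 8, n_groups = 2,
                         loading_sd = 1) {
  m <- matrix(20 + rep(rnorm(n_samples, 0, loading_sd), each = n_genes) +
                rnorm(n_genes * n_samples, 0, 0.5),
              n_genes, n_samples,
              dimnames = list(paste0("g", seq_len(n_genes)),
                              paste0("s", seq_len(n_samples))))
  grp <- rep(paste0("grp", seq_len(n_groups)), length.out = n_samples)
  ct_table(m, groups = grp)
}

# deterministic 6-group fixture with a target, two flat references and
# two references carrying strong group effects (the "bad" pair)
swap_fixture <- function() {
  groups <- rep(c("foregut", "midgut", "hindgut", "epidermis",
                  "trachea", "antenna"), each = 3)
  rep_off <- rep(c(-0.05, 0, 0.05), times = 6)    # mild replicate wobble
  target_shift <- c(foregut = 0, midgut = -2, hindgut = -2,
                    epidermis = -1, trachea = -2, antenna = 0)
  bad_shift <- c(foregut = 1.5, midgut = 0.5, hindgut = -0.5,
                 epidermis = 2.5, trachea = -2, antenna = 0.5)
  m <- rbind(UAP = 24 + target_shift[groups] + rep_off,
             R1 = 18 + rep_off, R2 = 20 + rep_off,
             U1 = 19 + bad_shift[groups] + rep_off,
             U2 = 21 + bad_shift[groups] + rep_off)
  colnames(m) <- paste0(groups, "_r", rep(1:3, 6))
  ct_table(m, groups = setNames(groups, colnames(m)))
}

write_long_csv <- function(t, path) {
  df <- data.frame(sample = rep(colnames(t$ct), each = nrow(t$ct)),
                   group = rep(t$groups, each = nrow(t$ct)),
                   gene = rep(rownames(t$ct), ncol(t$ct)),
                   replicate = 1L,
                   ct = as.vector(t$ct))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}
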