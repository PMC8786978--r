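## Shared oracles and miniature builders for the suite.

## central-difference gradient of a scalar function of an n x 3 matrix
num_grad <- function(fn, X, h = 1e-4) {
  G <- X * 0
  for (i in seq_len(nrow(X))) for (k in 1:3) {
    Xp <- X; Xp[i, k] <- X[i, k] + h
    Xm <- X; Xm[i, k] <- X[i, k] - h
    G[i, k] <- (fn(Xp) - fn(Xm)) / (2 * h)
  }
  G
}

## relative force/-gradient mismatch
grad_mismatch <- function(F, G) max(abs(F + G)) / max(max(abs(F)), 1e-12)

## small two-filament network with one branch, for force checks
branched_net <- function(perturb = 0, seed = 1) {
  set.seed(seed)
  net <- actin_network()
  net <- an_add_filament(net, cbind(0, 0, seq(0, 600, by = 150)))
  net <- nucleate_daughter(net, 1, 2, azimuth = 0.7)
  if (perturb > 0)
    net$X <- net$X + matrix(stats::rnorm(length(net$X), 0, perturb), ncol = 3)
  net
}

## one crosslinker row between segments of a network
one_linker <- function(kind = 3L, a1 = 1L, a2 = 2L, b1 = 3L, b2 = 4L,
                       alpha = 0.3, beta = 0.6, kappa = 10, L0 = 50,
                       filA = 1L, filB = 1L, nuc_node = 0L) {
  data.frame(kind = kind, filA = filA, a1 = a1, a2 = a2, alpha = alpha,
             filB = filB, b1 = b1, b2 = b2, beta = beta,
             kappa = kappa, L0 = L0, birth = 0, F_prev = 0,
             nuc_node = nuc_node)
}

## small ECM patch shared by several tests (cached per session)
.test_ecm <- local({
  cache <- new.env(parent = emptyenv())
  function(seed = 1) {
    key <- paste0("s", seed)
    if (is.null(cache[[key]]))
      cache[[key]] <- generate_network(c(8000, 8000, 8000), 2000, 41,
                                       seed = seed)
    cache[[key]]
  }
})
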