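# shared fixtures built in code

roi4 <- function() c("FP", "pSTS", "PCC", "rACC")

# small three-node DAG with strong edges, used across SEM tests
dag3 <- function() {
  nodes <- c("x", "y", "z")
  B <- matrix(0, 3, 3, dimnames = list(nodes, nodes))
  B["y", "x"] <- 0.7
  B["z", "y"] <- -0.6
  list(nodes = nodes, B = B, psi = c(1, 0.8, 1.2),
       model = path_model(nodes, rbind(c("x", "y"), c("y", "z"))))
}

# random stable coefficient matrix on p nodes (spectral radius < radius)
random_stable_B <- function(p, density = 0.4, radius = 0.8) {
  B <- matrix(0, p, p)
  off <- which(row(B) != col(B))
  pick <- off[stats::runif(length(off)) < density]
  B[pick] <- stats::rnorm(length(pick), sd = 0.5)
  rho <- roisem:::spectral_radius(B)
  if (rho >= radius) B <- B * (radius / rho) * 0.9
  B
}

# two-condition, two-ROI generating model for fast simulations
tiny_model <- function(...) {
  nodes <- c("STS", "FP")
  B <- matrix(0, 2, 2, dimnames = list(nodes, nodes))
  B["FP", "STS"] <- 0.5
  generating_model(nodes, list(neutral = matrix(0, 2, 2), care = B), ...)
}

expect_no_extra_rng <- function(x) x  # marker helper (readability only)
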