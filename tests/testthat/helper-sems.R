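# small SEM fixtures built in code

# Z -> X (a), Z -> Y (b), X -> Y (c), unit marginal variances
confounded_triangle <- function(a = 0.5, b = 0.5, c = 0.3) {
  labs <- c("Z", "X", "Y")
  W <- matrix(0, 3, 3, dimnames = list(labs, labs))
  W["Z", "X"] <- a; W["Z", "Y"] <- b; W["X", "Y"] <- c
  sem_spec(W)
}

# 4-node confounded SEM used for the coverage experiment:
# C -> X, C -> Y, X -> M, M -> Y
coverage_sem <- function() {
  labs <- c("C", "X", "M", "Y")
  W <- matrix(0, 4, 4, dimnames = list(labs, labs))
  W["C", "X"] <- 0.6; W["C", "Y"] <- 0.4
  W["X", "M"] <- 0.5; W["M", "Y"] <- 0.3
  sem_spec(W)
}

dag_of <- function(spec) causal_dag(spec$W, categories = spec$categories)
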