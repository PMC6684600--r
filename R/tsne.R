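# Exact t-SNE (no Barnes-Hut approximation).  The points being embedded are
# *features* described by their profiles across training samples, so the point
# count is the feature dimensionality d -- typically tens to a few thousand --
# and the O(d^2) exact gradient is both affordable and more accurate than tree
# approximations at this scale.
#
# Standard formulation: Gaussian conditional affinities in the input space
# with per-point bandwidths found by binary search to match a target
# perplexity, symmetrized; Student-t (df = 1) similarities in the plane;
# gradient descent on KL(P || Q) with early exaggeration and momentum.

# per-row bandwidth search: returns the symmetrized joint probabilities P
tsneAffinities <- function(D2, perplexity, tol = 1e-5, max_iter = 50L) {
    n <- nrow(D2)
    logU <- log(perplexity)
    P <- matrix(0, n, n)
    for (i in seq_len(n)) {
        beta <- 1
        betamin <- -Inf
        betamax <- Inf
        Di <- D2[i, -i]
        for (iter in seq_len(max_iter)) {
            Pi <- exp(-Di * beta)
            sumP <- sum(Pi)
            if (sumP < .Machine$double.xmin) sumP <- .Machine$double.xmin
            H <- log(sumP) + beta * sum(Di * Pi) / sumP
            if (abs(H - logU) < tol) break
            if (H > logU) {
                betamin <- beta
                beta <- if (is.finite(betamax)) (beta + betamax) / 2 else beta * 2
            } else {
                betamax <- beta
                beta <- if (is.finite(betamin)) (beta + betamin) / 2 else beta / 2
            }
        }
        P[i, -i] <- Pi / sumP
    }
    P <- (P + t(P)) / (2 * n)
    pmax(P, .Machine$double.xmin)
}

# X: points x variables; returns points x 2 coordinates.
# Deterministic for fixed inputs: the only randomness is the N(0, 1e-4)
# initialization drawn from the caller-seeded stream.
tsneEmbed <- function(X, perplexity, max_iter = 500L, eta = 100,
                      exaggeration = 12, exaggerate_iter = 100L,
                      momentum = 0.5, final_momentum = 0.8,
                      momentum_switch = 250L) {
    n <- nrow(X)
    D2 <- as.matrix(dist(X))^2
    P <- tsneAffinities(D2, perplexity) * exaggeration
    Y <- matrix(rnorm(n * 2L, sd = 1e-2), n, 2L)
    V <- matrix(0, n, 2L)
    gains <- matrix(1, n, 2L)
    for (it in seq_len(max_iter)) {
        if (it == exaggerate_iter + 1L) P <- P / exaggeration
        sumY <- rowSums(Y^2)
        # 1 / (1 + ||y_i - y_j||^2)
        num <- 1 / (1 + outer(sumY, sumY, "+") - 2 * tcrossprod(Y))
        diag(num) <- 0
        Q <- pmax(num / sum(num), .Machine$double.xmin)
        W <- (P - Q) * num
        grad <- 4 * (diag(rowSums(W)) - W) %*% Y
        mom <- if (it < momentum_switch) momentum else final_momentum
        gains <- ifelse(sign(grad) != sign(V), gains + 0.2, gains * 0.8)
        gains[gains < 0.01] <- 0.01
        V <- mom * V - eta * gains * grad
        Y <- Y + V
        Y <- sweep(Y, 2L, colMeans(Y))
    }
    Y
}
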