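# Independent oracles and small fixtures used across test files.

# small reference-shaped atlas for fast tests
smallAtlas <- function(sizes = c(SMN = 10, DMN = 13, FPN = 8, ATN = 6,
                                 none = 13))
    syntheticAtlas(sizes)

# random symmetric weight matrix with zero diagonal
randomWeights <- function(n) {
    w <- matrix(rnorm(n * n), n)
    w <- (w + t(w)) / 2
    diag(w) <- 0
    dimnames(w) <- list(sprintf("R%02d", 1:n), sprintf("R%02d", 1:n))
    w
}

# random binary undirected graph
randomGraph <- function(n, p = 0.5) {
    a <- matrix(0L, n, n)
    a[upper.tri(a)] <- as.integer(runif(n * (n - 1) / 2) < p)
    a + t(a)
}

# oracle: all-pairs shortest path lengths by repeated neighborhood
# expansion (pure R, no BFS shared with the implementation)
oracleDistances <- function(a) {
    n <- nrow(a)
    if (n == 0) return(a)
    d <- matrix(Inf, n, n)
    diag(d) <- 0
    reach <- diag(n) > 0
    frontier <- reach
    for (step in seq_len(n)) {
        nxt <- (frontier %*% a) > 0
        new <- nxt & !reach
        if (!any(new)) break
        d[new] <- step
        reach <- reach | new
        frontier <- new
    }
    d
}

# oracle: global efficiency from the distance matrix
oracleGE <- function(a) {
    n <- nrow(a)
    if (n <= 1) return(0)
    d <- oracleDistances(a)
    sum(1 / d[row(d) != col(d)]) / (n * (n - 1))
}

# oracle: adaptive degree-targeted attack recomputed from scratch
oracleAttack <- function(a) {
    n <- nrow(a)
    alive <- seq_len(n)
    ge <- numeric(n)
    ge[1] <- oracleGE(a)
    for (k in seq_len(n - 1)) {
        deg <- rowSums(a[alive, alive, drop = FALSE])
        victim <- alive[which.max(deg)]  # ties: first = lowest index
        alive <- setdiff(alive, victim)
        ge[k + 1] <- oracleGE(a[alive, alive, drop = FALSE])
    }
    ge
}

# oracle: Johnson-Neyman boundaries by dense grid + bisection on the
# conditional-effect t statistic, recomputed from the model directly
oracleJNBoundaries <- function(fit, alpha = 0.05, gridN = 1e5) {
    cf <- coef(fit@model)
    V <- vcov(fit@model)
    b1 <- cf[[fit@natTerm]]
    b3 <- cf[[fit@intTerm]]
    tc <- qt(1 - alpha / 2, fit@model$df.residual)
    f <- function(w)
        abs((b1 + b3 * w) /
            sqrt(V[fit@natTerm, fit@natTerm] +
                 w^2 * V[fit@intTerm, fit@intTerm] +
                 2 * w * V[fit@natTerm, fit@intTerm])) - tc
    rng <- range(fit@model$model[[fit@modTerm]])
    w <- seq(rng[1], rng[2], length.out = gridN)
    y <- f(w)
    flips <- which(y[-1] * y[-gridN] < 0)
    vapply(flips, function(i)
        uniroot(f, c(w[i], w[i + 1]), tol = 1e-10)$root, numeric(1))
}

# one-row PD profile for generator tests
pdProfile <- function(dat = -3.6, education = 15.8, pa = 50,
                      sequence = 2, id = "PD01", idx = 1) {
    data.frame(id = id, idx = idx, group = "PD", age = 62, sex = "m",
               education = education, putaminalDaT = dat, pa = pa,
               sequence = sequence,
               nVolumes = c(740L, 500L, 740L)[sequence],
               stringsAsFactors = FALSE)
}

# mean within-network sample correlation of a time-series matrix
meanWithinCor <- function(ts, atlas, network) {
    m <- networkLabels(atlas) == network
    r <- cor(t(ts[m, , drop = FALSE]))
    mean(r[upper.tri(r)])
}

# simulate NAT records from the beta GLMM itself (known coefficients)
simulateBetaNAT <- function(cohort, b0 = -1, bDensity = 0.6, bDat = 0,
                            bPA = 0, bEdu = 0, bAge = 0, bSexM = 0,
                            bSeq2 = 0, bSeq3 = 0, phi = 60, tau = 0.3,
                            network = "SMN") {
    pd <- cohort[cohort$group == "PD", ]
    u <- setNames(rnorm(nrow(pd), 0, tau), pd$id)
    grid <- expand.grid(participant = pd$id, density = natDensities(),
                        stringsAsFactors = FALSE)
    g <- merge(grid, pd, by.x = "participant", by.y = "id")
    eta <- b0 + bDensity * g$density + bDat * g$putaminalDaT +
        bPA * g$pa + bEdu * g$education + bAge * g$age +
        bSexM * (g$sex == "m") + bSeq2 * (g$sequence == 2) +
        bSeq3 * (g$sequence == 3) + u[g$participant]
    mu <- plogis(eta)
    data.frame(participant = g$participant, network = network,
               density = g$density,
               nat = rbeta(nrow(g), mu * phi, (1 - mu) * phi),
               stringsAsFactors = FALSE)
}

# moderation-model data with a planted interaction
makeModData <- function(n, bNat = 5, bPA = 0.05, bInt = 0.5,
                        noise = 1) {
    d <- data.frame(
        participant = sprintf("P%03d", seq_len(n)),
        natMean = runif(n, 0.2, 0.8),
        pa = rlnorm(n, log(50), 0.8),
        education = rnorm(n, 16, 3),
        putaminalDaT = rnorm(n, -3.6, 0.7),
        age = rnorm(n, 62, 8),
        sex = sample(c("f", "m"), n, TRUE),
        sequence = sample(1:3, n, TRUE, prob = c(0.2, 0.7, 0.1)),
        stringsAsFactors = FALSE)
    d$gmp <- 2 + bNat * d$natMean + bPA * d$pa +
        bInt * d$natMean * d$pa - 0.1 * d$age + rnorm(n, 0, noise)
    d$gcp <- rnorm(n, 0, noise)  # null cognitive outcome
    d
}
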