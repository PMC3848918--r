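# Shared helpers: a cached registry, range builders around known truth, and
# oracle values frozen from independent high-precision evaluation (scipy
# closed forms; DOP853 at rtol 1e-12 for the spheroid ODE).

REG <- defaultRegistry()

# box spanning one order of magnitude around each true value (sqrt(10) each
# way); zero-valued truths get a symmetric [-1, 1] box
rangesAroundTruth <- function(truth, init = character(0)) {
  do.call(rbind, lapply(names(truth), function(nm) {
    v <- truth[[nm]]
    if (v == 0) parameterSpec(nm, -1, 1, init = nm %in% init)
    else if (v > 0) parameterSpec(nm, v / sqrt(10), v * sqrt(10),
                                  init = nm %in% init)
    else parameterSpec(nm, v * sqrt(10), v / sqrt(10), init = nm %in% init)
  }))
}

noiselessSeries <- function(modelId, truth, tStart, tStop, tStep) {
  tm <- seq(tStart, tStop, by = tStep)
  simulateModel(REG, modelId, truth, tm)
}

maxRelErr <- function(est, truth, skip = character(0)) {
  keep <- setdiff(names(truth), skip)
  max(abs(est[keep] - unlist(truth)[keep]) /
        pmax(abs(unlist(truth)[keep]), 1e-12))
}

# frozen oracle values (independent scipy evaluation)
ORACLE <- list(
  gompertz_A2      = 0.9948843628273195,   # (A=2, muMax=.5, lambda=1), t=3
  logistic_t10     = 0.9820137900379085,   # (A=1, muMax=.25, lambda=4), t=10
  richards_t8      = 0.9897728218116805,   # (A=1, muMax=.3, lambda=2, v=.5), t=8
  baranyi_printed  = 5.991638683063612,    # (0, 9, .8, v=.5, h0=2, m=1), t=10
  baranyi_classic  = 4.851644296238142,    # same params, 1/v adjustment
  baranyi_m2       = 5.793968936345179,    # (.1, 8, .6, v=.9, h0=1.5, m=2), t=12
  h3_t20           = 0.6630132162727644,   # published params, P0=.05, t0=0
  h3_t40           = 1.9528908355453467,
  h3_t62           = 5.422224348281893,
  lcf_r10          = 0.8386687270512182,   # (a=.2, d=.05, lam=1, r0=.5)
  lcf_r20          = 1.3140385893914777,
  lcf_r40          = 2.6107214512681476
)

# H3 parameter set reported for the carcinoma weight series, used as a
# synthetic operating point (the original series itself is external data)
H3_REPORTED <- c(M = 7.547, delta = 5.103e-9, gamma = 4.630, theta = 0.004,
                 P0 = 0.05, t0 = 0)
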