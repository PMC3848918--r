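# Default parameter search ranges for the built-in model catalogue.
# Units: time axis in the user's time unit (hours for typical plate-reader
# growth curves, days for tumor series); signal in the measurement's unit
# (OD, radius, weight).  `init: true` flags initial-condition parameters,
# whose start value defaults to the first data point during fitting.
gompertz:
  parameters:
    A:      {lower: 0.05, upper: 10.0, guess: 1.0}
    muMax:  {lower: 0.005, upper: 5.0, guess: 0.2}
    lambda: {lower: 0.0, upper: 24.0, guess: 2.0}
logistic:
  parameters:
    A:      {lower: 0.05, upper: 10.0, guess: 1.0}
    muMax:  {lower: 0.005, upper: 5.0, guess: 0.2}
    lambda: {lower: 0.0, upper: 24.0, guess: 2.0}
richards:
  parameters:
    A:      {lower: 0.05, upper: 10.0, guess: 1.0}
    muMax:  {lower: 0.005, upper: 5.0, guess: 0.2}
    lambda: {lower: 0.0, upper: 24.0, guess: 2.0}
    v:      {lower: 0.05, upper: 10.0, guess: 1.0}
baranyi:
  parameters:
    y0:     {lower: -5.0, upper: 5.0, guess: 0.0, init: true}
    yMax:   {lower: 0.0, upper: 15.0, guess: 9.0}
    muMax:  {lower: 0.01, upper: 5.0, guess: 0.5}
    vRate:  {lower: 0.01, upper: 5.0, guess: 0.5}
    h0:     {lower: 0.0, upper: 10.0, guess: 2.0}
    mCurv:  {lower: 0.1, upper: 10.0, guess: 1.0}
baranyi_classic:
  parameters:
    y0:     {lower: -5.0, upper: 5.0, guess: 0.0, init: true}
    yMax:   {lower: 0.0, upper: 15.0, guess: 9.0}
    muMax:  {lower: 0.01, upper: 5.0, guess: 0.5}
    vRate:  {lower: 0.01, upper: 5.0, guess: 0.5}
    h0:     {lower: 0.0, upper: 10.0, guess: 2.0}
    mCurv:  {lower: 0.1, upper: 10.0, guess: 1.0}
h3:
  parameters:
    M:      {lower: 0.1, upper: 20.0, guess: 8.0}
    delta:  {lower: 0.0, upper: 1.0e-4, guess: 1.0e-8}
    gamma:  {lower: 0.5, upper: 8.0, guess: 4.0}
    theta:  {lower: 0.0, upper: 1.0, guess: 0.005}
    P0:     {lower: 1.0e-4, upper: 5.0, guess: 0.05, init: true}
    t0:     {lower: 0.0, upper: 100.0, guess: 0.0, init: true}
lcf:
  parameters:
    alpha:       {lower: 0.005, upper: 2.0, guess: 0.2}
    delta:       {lower: 0.001, upper: 1.0, guess: 0.05}
    lambdaDepth: {lower: 0.01, upper: 100.0, guess: 1.0}
    r0:          {lower: 0.001, upper: 50.0, guess: 0.5, init: true}
poly1:
  parameters:
    c0: {lower: -100.0, upper: 100.0, guess: 0.0}
    c1: {lower: -100.0, upper: 100.0, guess: 0.1}
poly2:
  parameters:
    c0: {lower: -100.0, upper: 100.0, guess: 0.0}
    c1: {lower: -100.0, upper: 100.0, guess: 0.1}
    c2: {lower: -100.0, upper: 100.0, guess: 0.01}
exp_decay:
  parameters:
    y0:     {lower: 0.001, upper: 100.0, guess: 1.0, init: true}
    k:      {lower: 1.0e-4, upper: 5.0, guess: 0.3}
    offset: {lower: -10.0, upper: 100.0, guess: 0.0}
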