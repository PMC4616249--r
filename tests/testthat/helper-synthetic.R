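# shared fixture builders; everything is generated in code at test time

# homogeneous-Poisson spike train on [0, dur)
rPoissonTrain <- function(rate, dur) {
  n <- rpois(1L, rate * dur)
  sort(runif(n, 0, dur))
}

# one trial of a unit with a rate step of `gain` x baseline on
# [0, stepDur) after the alignment time t0; window spans [-7, 3] s
stepTrial <- function(t0, baseline = 10, gain = 1, stepDur = 0.5) {
  seg <- function(a, b, r) {
    n <- rpois(1L, r * (b - a))
    sort(runif(n, t0 + a, t0 + b))
  }
  c(seg(-7, 0, baseline), seg(0, stepDur, baseline * gain),
    seg(stepDur, 3, baseline))
}

# alignment grid with enough spacing for full baseline windows
alignGrid <- function(nTrials, spacing = 15, first = 20)
  seq(first, by = spacing, length.out = nTrials)

# brute-force oracle: all stride-1 windows of 3 consecutive IPIs whose sum
# is strictly below the bound (press index = IPI index + 3)
bruteForceTargets <- function(ipis, bound) {
  n <- length(ipis)
  if (n < 3L) return(integer())
  hits <- integer()
  for (i in 1:(n - 2L))
    if (ipis[i] + ipis[i + 1L] + ipis[i + 2L] < bound)
      hits <- c(hits, i + 3L)
  hits
}

# small Gaussian waveform cloud: n snippets around a template
wfCloud <- function(n, template, noiseSd = 1, shift = 0) {
  matrix(rep(template + shift, each = n), n) +
    matrix(rnorm(n * length(template), 0, noiseSd), n)
}

tinyBehaviorParams <- function(nSessions = 3L)
  behaviorGenParams(
    nSessions = nSessions,
    targetFrequencies = c(0, 1.5, 4.5)[seq_len(nSessions)],
    sequencesPerMin = rep(3, nSessions),
    lengthMean = seq(1, 4, length.out = nSessions),
    lengthDispersion = c(50, 5, 2)[seq_len(nSessions)],
    ipiMedian = c(0.6, 0.4, 0.25)[seq_len(nSessions)],
    ipiLogSd = seq(0.4, 0.2, length.out = nSessions),
    sessionDuration = 300)
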