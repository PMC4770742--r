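# Independent brute-force oracle for the one-tailed Fisher test:
# enumerate the upper tail of the hypergeometric distribution directly
# from binomial coefficients, never through phyper().
bruteUpperTailP <- function(nCaseGood, nCaseBad, nCtrlGood, nCtrlBad) {
    N <- nCaseGood + nCaseBad + nCtrlGood + nCtrlBad
    K <- nCaseGood + nCtrlGood          # total good responses
    n <- nCaseGood + nCaseBad           # case draws
    xs <- nCaseGood:min(K, n)
    sum(exp(lchoose(K, xs) + lchoose(N - K, n - xs) - lchoose(N, n)))
}

expectedScore <- function(cg, cb, tg, tb) (cg / (cg + cb)) * (tb / (tg + tb))
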