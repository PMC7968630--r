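{
  "horizon": 60,
  "os": {
    "cluster1": {
      "estimate": 0.8,
      "lower": 0.203809263267639,
      "upper": 0.969179788866743
    },
    "cluster2": {
      "estimate": 0,
      "lower": "NA",
      "upper": "NA"
    }
  },
  "logrank": {
    "chi_square": 1.68463611859838,
    "p": 0.194309558676173
  },
  "cox": [
    {
      "covariate": "cluster2",
      "coef": 2.36681948869549,
      "se": 1.67144194190613,
      "hr": 10.6634231552568,
      "lower": 0.402867917179868,
      "upper": 282.247825004391,
      "z": 1.41603452046701,
      "p": 0.156765397660988,
      "_row": "cluster2"
    },
    {
      "covariate": "ipssr",
      "coef": -0.922875222343388,
      "se": 1.00093199959782,
      "hr": 0.397374855914943,
      "lower": 0.055873454156793,
      "upper": 2.82615024426987,
      "z": -0.922015903891774,
      "p": 0.356520280081031,
      "_row": "ipssr"
    }
  ]
}
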