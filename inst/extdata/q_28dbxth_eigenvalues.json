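{
 "name": "q_28dbxth_eigenvalues",
 "provenance": "Printed characteristic values of the 2,8-dibromoxanthone correction matrix, in printed order; includes negative values, which a Gram matrix cannot have (documented discrepancy).",
 "values": [
  -9.3541,
  -6.5978,
  -4.5987,
  -2.2512,
  -1.3575,
  -1.03279,
  -0.80915,
  -0.6308,
  5.1485,
  7.9062,
  11.3299,
  16.0541,
  19.1825,
  21.9817,
  22.3654,
  36.3718,
  58.2157
 ]
}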