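# Generator preset reproducing the study's sample shape: 33 villages in
# three market-sheds, 652 distinct households, 302 interviewed in both
# seasons (472 dry + 482 wet = 954 mother-season rows).
study_shape: true
seed: 1
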