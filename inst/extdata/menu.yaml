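# Example 4-cluster x 3-item vending menu; items within a cluster are
# listed in on-screen order (left, middle, right).
up: [pizza, burger, hotdog]
down: [drumstick, chips, popcorn]
left: [coffee, tea, cocoa]
right: [cola, water, juice]
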