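{"destinations":{"room_1":[2,4],"room_2":[2,14],"room_3":[2,24],"room_4":[11,4],"room_5":[11,14],"room_6":[11,24]},"nurse_stations":[[7,9],[7,21]],"cell_size_m":1}
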