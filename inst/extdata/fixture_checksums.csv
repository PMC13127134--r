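"file","md5"
"table1_incidence.csv","68999dc1ff5b00b5d65abf8fffcc2901"
"table2_contacts.csv","6a9f98264ac3130cda674d37a0d7b19d"
"table3_costs.csv","eab327c4b51496a30d08ca1bae57a665"
"printed_results.csv","ad20c9d73ca3c78e8dceb1eb5ed0c9b6"
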