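affc6cffae2d17ddd32f6dee79938d89  table1_devices.csv
5eb2ef4196a072b8dd613cb2136f775a  table2_patients.csv
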