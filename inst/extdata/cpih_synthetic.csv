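year,index
2017,104.1
2018,106.5
2019,108.3
2020,109.4
2021,112.1
2022,121.1
2023,129.3
2024,133.4
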