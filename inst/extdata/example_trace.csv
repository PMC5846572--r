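timestamp,glucose
2000-01-01T00:00:00Z,112.0
2000-01-01T00:05:00Z,115.4
2000-01-01T00:10:00Z,119.8
2000-01-01T00:15:00Z,126.1
2000-01-01T00:20:00Z,134.0
2000-01-01T00:25:00Z,143.6
2000-01-01T00:30:00Z,151.2
2000-01-01T00:35:00Z,158.9
2000-01-01T00:40:00Z,163.5
2000-01-01T00:45:00Z,165.0
2000-01-01T00:50:00Z,162.2
2000-01-01T00:55:00Z,155.7
2000-01-01T01:00:00Z,147.3
2000-01-01T01:25:00Z,118.9
2000-01-01T01:30:00Z,114.2
2000-01-01T01:35:00Z,110.8
2000-01-01T01:40:00Z,108.5
2000-01-01T01:45:00Z,107.1
2000-01-01T01:50:00Z,106.3
2000-01-01T01:55:00Z,105.9
2000-01-01T02:00:00Z,105.6
2000-01-01T02:05:00Z,105.2
2000-01-01T02:10:00Z,104.9
2000-01-01T02:15:00Z,104.8
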