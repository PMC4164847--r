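format: 1
alternatives:
- road
- cableway
nodes:
  A:
    label: Sustainable forest harvesting
    children:
    - B1
    - B2
    - B3
  B1:
    label: Ecological benefits
    children:
    - C11
    - C12
    - C13
    weight: 0.5954
  B2:
    label: Economic benefits
    children:
    - C21
    - C22
    - C23
    weight: 0.2763
  B3:
    label: Social benefits
    children:
    - C31
    - C32
    - C33
    weight: 0.1283
  C11:
    label: Natural ecology
    children:
    - D1
    - D2
    - D3
    - D4
    - D5
    weight: 0.2763
  C12:
    label: Ecological protection
    children:
    - D6
    - D7
    - D8
    - D9
    weight: 0.5954
  C13:
    label: Ecological environment
    children:
    - D10
    - D11
    - D12
    - D13
    weight: 0.1283
  C21:
    label: Cost of production
    children:
    - D14
    - D15
    - D16
    weight: 0.3011
  C22:
    label: Production efficiency
    children:
    - D17
    - D18
    - D19
    weight: 0.4536
  C23:
    label: Input of production
    children:
    - D20
    - D21
    - D22
    weight: 0.2453
  C31:
    label: Forest resources
    children:
    - D23
    - D24
    - D25
    - D26
    weight: 0.2392
  C32:
    label: Technological education
    children:
    - D27
    - D28
    - D29
    - D30
    - D31
    - D32
    - D33
    - D34
    - D35
    weight: 0.4422
  C33:
    label: Humanization index
    children:
    - D36
    - D37
    - D38
    - D39
    weight: 0.3186
  D1:
    label: Integrity of forestry landscape
    direction: positive
    weight: 0.0647
  D2:
    label: Diversity index
    direction: positive
    weight: 0.1665
  D3:
    label: Plantation productivity
    direction: positive
    weight: 0.331
  D4:
    label: Fertility index
    direction: positive
    weight: 0.331
  D5:
    label: Stability index
    direction: positive
    weight: 0.1068
  D6:
    label: Water source conservation
    direction: positive
    weight: 0.2046
  D7:
    label: Soil and water conservation
    direction: positive
    weight: 0.3403
  D8:
    label: Air purifying
    direction: positive
    weight: 0.2505
  D9:
    label: Soil improving
    direction: positive
    weight: 0.2046
  D10:
    label: Biomass of forest
    direction: positive
    weight: 0.3309
  D11:
    label: Defending the remaining woods
    direction: positive
    weight: 0.1794
  D12:
    label: Afforestation effect
    direction: positive
    weight: 0.2201
  D13:
    label: Vegetation coverage
    direction: positive
    weight: 0.2696
  D14:
    label: Unit cost for ready (100 million yuan)
    direction: reverse
    weight: 0.3106
  D15:
    label: Saving rate of unit cost
    direction: positive
    weight: 0.4361
  D16:
    label: Pollution controlled cost (100 million yuan)
    direction: reverse
    weight: 0.2533
  D17:
    label: Utilization rate of forest resources
    direction: positive
    weight: 0.4361
  D18:
    label: Utilization rate of equipment
    direction: positive
    weight: 0.3106
  D19:
    label: Per capita work efficiency (m3/man)
    direction: positive
    weight: 0.2533
  D20:
    label: Increment of value of annual forest production (10,000 yuan)
    direction: positive
    weight: 0.2224
  D21:
    label: Annual proportion of fixed investment (%)
    direction: positive
    weight: 0.3357
  D22:
    label: Annual proportion of construction investment (%)
    direction: positive
    weight: 0.4419
  D23:
    label: Forestry area (10,000 hm2)
    direction: positive
    weight: 0.1793
  D24:
    label: Unit area amount of growing stock (m3/hm2)
    direction: positive
    weight: 0.2201
  D25:
    label: Forestry land area (10,000 hm2)
    direction: positive
    weight: 0.2696
  D26:
    label: Structural integrity of forestry
    direction: positive
    weight: 0.331
  D27:
    label: Improvement of scientific level
    direction: graded
    weight: 0.1376
  D28:
    label: Improvement of educational level
    direction: positive
    weight: 0.1201
  D29:
    label: Policies and regulations
    direction: positive
    weight: 0.1049
  D30:
    label: Benefit future generations
    direction: positive
    weight: 0.1614
  D31:
    label: Benefit other industries
    direction: positive
    weight: 0.126
  D32:
    label: Numbers of professionals
    direction: positive
    weight: 0.1026
  D33:
    label: Ratio of trained staff to entire staff
    direction: positive
    weight: 0.0781
  D34:
    label: Investment of science and technology project and key laboratory
    direction: positive
    weight: 0.0804
  D35:
    label: Number of science and technology projects
    direction: positive
    weight: 0.0889
  D36:
    label: Reducing labor intensity
    direction: graded
    weight: 0.1931
  D37:
    label: Advancement of operation and technology
    direction: positive
    weight: 0.3205
  D38:
    label: Operation technical safety
    direction: positive
    weight: 0.2248
  D39:
    label: Harmony of man-machine environment
    direction: positive
    weight: 0.2616
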