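{
  "schema": "pclcbench-anfis-1",
  "premise_error": [
    [15.2094104140572, 1.99505954984582, -48.2130472397106],
    [14.8110470958549, 2.08206266996864, -19.1456090757698],
    [12.8027384416003, 2.0540277940709, 10.951882687349]
  ],
  "premise_rate": [
    [0.201651253036502, 2.00444196341476, -0.392648524926628],
    [0.198967265465698, 1.9907781168601, 1.395752084562e-08],
    [0.200895363153636, 2.00046222564859, 0.396491074539191]
  ],
  "consequents": [
    [-0.025901526672315, -0.9860400922853, 3.34792870609549],
    [-0.0324679260124382, -1.37130478921497, 2.87207903002604],
    [-0.0304268466611687, -1.46526776582727, 2.96603955127387],
    [-0.0268055796629569, -1.72810873160052, 2.83402880168359],
    [-0.030699876981949, -1.65684971391033, 2.84669355536863],
    [-0.0265963441584905, -1.51472586241235, 2.95916574551214],
    [-0.0674833738078465, -0.737434847711036, 2.22404628568575],
    [-0.0919006131719117, -0.907021093156314, 1.97705056672872],
    [-0.0678291386615681, -1.45120390076225, 1.89124421116861]
  ],
  "meta": {
    "train_rmse": 0.0229630708350939,
    "test_rmse": 0.0333687649581117,
    "epochs": 6,
    "seed": 42
  }
}
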