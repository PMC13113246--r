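{
  "schema": "pclcbench-anfis-1",
  "premise_error": [
    [15.2314010636177, 1.99536390498349, -47.972301887795],
    [14.9390467047575, 2.0804060756462, -18.9118011942958],
    [12.8351387906765, 2.04129808630617, 10.9759130671229]
  ],
  "premise_rate": [
    [0.217926837097675, 2.00244498902953, -0.396522977388349],
    [0.216470745144179, 1.99683754112283, 0.0340832428340602],
    [0.217121796554311, 2.00008433967286, 0.467621494294728]
  ],
  "consequents": [
    [-0.0190586179534894, -2.47040813330636, 2.75374955383774],
    [-0.0194624028024289, -2.4766243806443, 2.7202080906087],
    [-0.0181830181786522, -2.46817694642692, 2.76769741543243],
    [-0.017115236665281, -2.66862032426324, 2.63399917899825],
    [-0.0179251685140365, -2.6331073399829, 2.68396499522782],
    [-0.0165899695246388, -2.66226593900717, 2.77656218757485],
    [-0.0454473777003472, -1.93530528104328, 2.26998032166445],
    [-0.0545110849079863, -1.82438083687581, 2.02604085035934],
    [-0.0448263192193994, -1.99697261138999, 1.79535013246933]
  ],
  "meta": {
    "train_rmse": 0.0161715515556597,
    "test_rmse": 0.0209861692726361,
    "epochs": 6,
    "seed": 43
  }
}
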